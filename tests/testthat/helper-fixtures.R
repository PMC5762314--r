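# shared tiny fixtures, built in code

two_types <- cell_type_set(c("ALDHpos", "ALDHneg"))

# small fixed two-type histogram: ALDH+ parents produce (1,0) twice as often
# as (0,2) or (1,1); ALDH- parents produce only ALDH- cells or nothing
make_test_dist <- function(period_hours = 72) {
  offspring_distribution(
    two_types,
    histograms = list(
      ALDHpos = list(vectors = rbind(c(1L, 0L), c(0L, 2L), c(1L, 1L)),
                     frequency = c(2, 1, 1)),
      ALDHneg = list(vectors = rbind(c(0L, 0L), c(0L, 1L), c(0L, 2L)),
                     frequency = c(1, 2, 1))
    ),
    period_hours = period_hours
  )
}

# degenerate histogram: every parent of either type produces exactly `vec`
make_point_dist <- function(vec_pos, vec_neg = vec_pos, period_hours = 72) {
  offspring_distribution(
    two_types,
    histograms = list(
      ALDHpos = list(vectors = rbind(as.integer(vec_pos)), frequency = 1),
      ALDHneg = list(vectors = rbind(as.integer(vec_neg)), frequency = 1)
    ),
    period_hours = period_hours
  )
}

make_death <- function(gpos = 0, gneg = gpos) {
  death_model(c(ALDHpos = gpos, ALDHneg = gneg), two_types)
}

make_config <- function(dist = make_test_dist(), death = make_death(),
                        initial = c(ALDHpos = 50, ALDHneg = 50),
                        horizon = 2L, replicates = 5L, seed = 42L, ...) {
  scenario_config(two_types, initial, dist, death,
                  horizon = horizon, replicates = replicates, seed = seed, ...)
}
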