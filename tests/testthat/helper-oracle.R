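# Independent brute-force oracle: red cells and plasma kept as two separate
# tallies; every event edits the tallies directly and the hematocrit is
# recomputed as a ratio at the end. Deliberately shares no code with the
# package's closed forms or event engine.

oracle_state <- function(bv, hct) {
  list(rbc = bv * hct / 100, plasma = bv * (1 - hct / 100))
}

oracle_hct <- function(s) 100 * s$rbc / (s$rbc + s$plasma)

oracle_bv <- function(s) s$rbc + s$plasma

oracle_apply <- function(s, kind, volume = 0, donor_hct = NULL,
                         baseline_bv = NULL, packed_hct = 0.65) {
  h <- s$rbc / (s$rbc + s$plasma)
  switch(kind,
    blood_loss = {
      s$rbc <- s$rbc - h * volume
      s$plasma <- s$plasma - (1 - h) * volume
    },
    crystalloid_in = s$plasma <- s$plasma + volume,
    urine_out = ,
    insensible_out = ,
    dehydration = s$plasma <- s$plasma - volume,
    whole_blood_in = {
      s$rbc <- s$rbc + donor_hct / 100 * volume
      s$plasma <- s$plasma + (1 - donor_hct / 100) * volume
    },
    packed_rbc_in = {
      s$rbc <- s$rbc + packed_hct * volume
      s$plasma <- s$plasma + (1 - packed_hct) * volume
    },
    equilibrate_to_baseline = s$plasma <- baseline_bv - s$rbc,
    stop("oracle: unknown kind ", kind))
  s
}

# random valid (bv, hct) draws used by property tests
draw_states <- function(n, bv_range = c(50, 10000), hct_range = c(5, 65)) {
  data.frame(bv = runif(n, bv_range[1], bv_range[2]),
             hct = runif(n, hct_range[1], hct_range[2]))
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
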