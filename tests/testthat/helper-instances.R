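# shared fixtures, all generated in code

worked_draft <- function() draft_genome(list(c(1, 4), c(-5, 6), c(3, 2)))
worked_ref <- function() reference_genome(1:6)

# a random solvable instance: rearranged identity, fragmented
random_instance <- function(n_max = 6L, m_max = 3L, delta_max = 4L, n_min = 2L) {
  n <- sample(n_min:n_max, 1L)
  m <- sample(seq_len(min(m_max, n)), 1L)
  truth <- random_rearranged_genome(n, sample(0:delta_max, 1L))
  list(draft = fragment_genome(truth, m), ref = reference_genome(seq_len(n)),
       truth = truth, n = n, m = m)
}

# random permutation of a ground set as a perm object
random_perm <- function(elems) {
  elems <- sort(unique(as.integer(elems)))
  blockorder:::new_perm(elems, sample(elems))
}

# factor multiset of an event, orientation-free: each 2-cycle rotated to
# its canonical leader, then sorted
factor_multiset <- function(ev) {
  fs <- lapply(ev$factors, blockorder:::rotate_cycle_canonical)
  fs <- vapply(fs, paste, character(1), collapse = ",")
  sort(fs)
}

expect_factors <- function(ev, printed) {
  want <- sort(vapply(printed, function(f) {
    paste(blockorder:::rotate_cycle_canonical(as.integer(f)), collapse = ",")
  }, character(1)))
  testthat::expect_identical(factor_multiset(ev), unname(want))
}
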