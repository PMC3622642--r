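# end-to-end solver

test_that("the worked example solves with one reversal and one block-interchange", {
  fit <- block_order(worked_draft(), worked_ref())
  expect_identical(fit$distance, 3L)
  expect_identical(fit$n_rev, 1L)
  expect_identical(fit$n_bi, 1L)
  expect_identical(fit$assembly, c(1L, 4L, -5L, 6L, 3L, 2L))
  expect_identical(vapply(fit$events, `[[`, character(1), "kind"),
                   c("cap_exchange", "fusion", "fusion_alt", "reversal",
                     "block_interchange"))
  expect_identical(fit$blocks$index, 1:3)
  expect_identical(fit$blocks$orientation, rep(1L, 3))
})

test_that("trivial and orientation-only instances cost nothing", {
  fit <- block_order(draft_genome(list(c(1, 2, 3))), reference_genome(1:3))
  expect_identical(fit$distance, 0L)
  expect_identical(length(fit$events), 0L)

  fit <- block_order(list(2L, 1L), 1:2)
  expect_identical(fit$distance, 0L)

  # a draft that is the reverse complement of the reference is the same molecule
  fit <- block_order(list(c(-2L, -1L)), 1:2)
  expect_identical(fit$distance, 0L)
  fit <- block_order(list(-1L, 2L, -3L), 1:3)
  expect_identical(fit$distance, 0L)
})

test_that("arbitrary reference labels are supported via relabeling", {
  ref <- reference_genome(c(3L, -1L, 2L))
  fit <- block_order(draft_genome(list(c(3L, -1L), 2L)), ref)
  expect_identical(fit$distance, 0L)
  expect_true(identical(fit$assembly, c(3L, -1L, 2L)) ||
              identical(fit$assembly, c(-2L, 1L, -3L)))
})

test_that("after the cap-exchange phase every cycle has at most one T and one C3", {
  set.seed(101)
  for (k in 1:100) {
    inst <- random_instance()
    st <- blockorder:::solver_init(inst$draft, inst$ref)
    st <- blockorder:::cap_exchange_phase(st)
    for (cy in perm_cycles(st$prod)) {
      ch <- genome_char(cy, st$g)
      expect_lte(sum(ch == "T"), 1L)
      expect_lte(sum(ch == "C3"), 1L)
    }
  }
})

test_that("the fusion phase applies exactly m-1 fusions and reversals/BIs shrink the norm", {
  set.seed(103)
  for (k in 1:30) {
    inst <- random_instance()
    st <- blockorder:::solver_init(inst$draft, inst$ref)
    st <- blockorder:::cap_exchange_phase(st)
    st <- blockorder:::fusion_phase(st)
    kinds <- vapply(st$events, `[[`, character(1), "kind")
    expect_identical(sum(kinds %in% c("fusion", "fusion_alt")), inst$m - 1L)
    expect_identical(st$norm_after_fusion %% 2L, 0L)

    # each reversal decreases the quotient norm by exactly 2, each
    # block-interchange by exactly 4
    repeat {
      cand <- blockorder:::find_reversal(st)
      if (is.null(cand)) break
      n0 <- perm_norm(st$prod)
      st <- blockorder:::solver_apply(st, build_reversal(st$g, cand[1], cand[2]))
      expect_identical(perm_norm(st$prod), n0 - 2L)
    }
    st <- blockorder:::block_interchange_phase(st)  # asserts the -4 drop itself
    expect_true(perm_is_identity(st$prod))
  }
})

test_that("distance_only equals the full solve on random instances", {
  set.seed(107)
  for (k in 1:50) {
    inst <- random_instance()
    expect_identical(block_distance(inst$draft, inst$ref),
                     block_order(inst$draft, inst$ref)$distance)
  }
})

test_that("the distance formula and the event log are mutually consistent", {
  set.seed(109)
  for (k in 1:40) {
    inst <- random_instance()
    fit <- block_order(inst$draft, inst$ref)
    expect_identical(fit$distance, fit$n_rev + 2L * fit$n_bi)
    expect_identical(fit$distance, fit$norm_after_fusion %/% 2L)

    # replaying the reversal/BI log on the assembly reaches the reference
    readings <- replay_events(fit)
    expect_identical(length(readings), fit$n_rev + fit$n_bi)
    final <- if (length(readings)) readings[[length(readings)]] else fit$assembly
    expect_true(identical(final, inst$ref$order) ||
                identical(final, -rev(inst$ref$order)))
  }
})

test_that("reversal events change the reading by exactly one signed segment reversal", {
  one_segment_reversal <- function(before, after) {
    diffpos <- which(before != after)
    if (!length(diffpos)) return(FALSE)
    i <- min(diffpos); j <- max(diffpos)
    identical(after[i:j], -rev(before[i:j])) &&
      identical(after[-(i:j)], before[-(i:j)])
  }
  set.seed(113)
  found <- 0L
  for (k in 1:40) {
    inst <- random_instance()
    fit <- block_order(inst$draft, inst$ref)
    if (fit$n_rev == 0L) next
    rl <- blockorder:::relabeler(fit$ref)
    g <- fit$post_fusion$g
    before <- rl$backward(uncap_assembly(g))
    for (ev in fit$events) {
      if (ev$weight == 0L) next
      g$perm <- perm_compose(event_product(ev, g$elems), g$perm)
      after <- rl$backward(uncap_assembly(g))
      if (ev$kind == "reversal") {
        found <- found + 1L
        expect_true(one_segment_reversal(before, after) ||
                    one_segment_reversal(-rev(before), after))
      }
      before <- after
    }
  }
  expect_gt(found, 5L)
})

test_that("structural invariants hold on every intermediate state (check mode)", {
  set.seed(127)
  for (k in 1:25) {
    inst <- random_instance()
    fit <- block_order(inst$draft, inst$ref, check = TRUE)  # errors on violation
    expect_true(all(fit$psi_changes %in% c(-2L, 0L, 2L)))
  }
})

test_that("the assembly uses every contig exactly once", {
  set.seed(131)
  for (k in 1:20) {
    inst <- random_instance()
    fit <- block_order(inst$draft, inst$ref)
    expect_identical(sort(fit$blocks$index), seq_len(inst$m))
    expect_identical(sort(abs(fit$assembly)), seq_len(inst$n))
  }
})

test_that("mismatched gene sets are rejected", {
  expect_error(block_order(list(c(1, 2)), 1:3), "different gene counts")
})
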