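# rearrangement events, anchored on the published worked trace

E12 <- setdiff(-12:12, 0L)

# states of the worked example at each stage, built by applying events
worked_states <- function() {
  g <- cap_draft(worked_draft())
  s <- cap_reference(worked_ref(), 3)
  prod <- perm_compose(s$perm, perm_inverse(g$perm))
  st <- list(g0 = g, prod0 = prod)
  ce <- build_cap_exchange(g, 10, 8)
  r <- apply_event(g, prod, ce)
  st$ce <- ce; st$g1 <- r$genome; st$prod1 <- r$prod
  fu <- build_fusion(st$g1, -5, 10)
  r <- apply_event(st$g1, st$prod1, fu)
  st$fu <- fu; st$g2 <- r$genome; st$prod2 <- r$prod
  af <- build_alt_fusion(st$g2, 3, 12, 8)
  r <- apply_event(st$g2, st$prod2, af)
  st$af <- af; st$g3 <- r$genome; st$prod3 <- r$prod
  rv <- build_reversal(st$g3, -4, 6)
  r <- apply_event(st$g3, st$prod3, rv)
  st$rv <- rv; st$g4 <- r$genome; st$prod4 <- r$prod
  st
}

test_that("cap exchange reproduces the published factors and leaves the genome unchanged", {
  st <- worked_states()
  expect_factors(st$ce, list(c(-8, -10), c(-4, -6), c(9, 7), c(10, 8)))
  expect_true(perm_equal(st$g1$perm, perm_parse(
    "(7,1,4,10)(-10,-4,-1,-7)(9,-5,6,8)(-8,-6,5,-9)(11,3,2,12)(-12,-2,-3,-11)",
    elems = E12)))
  expect_true(perm_equal(st$prod1, perm_parse(
    "(2,4)(-1,-3)(3,12)(-2,-11)(5,-5,10)(-4,-9,6)(9,7)(-10,-8)", elems = E12)))
  # gene content of every contig is untouched
  readings <- function(g) {
    sort(vapply(seq_len(g$m), function(i) {
      cy <- blockorder:::cycle_of(g$perm, five_cap(g$n + 2L * i - 1L, g))
      paste(abs(cy[abs(cy) <= g$n]), collapse = ",")
    }, character(1)))
  }
  expect_identical(readings(st$g1), readings(st$g0))
  expect_error(build_cap_exchange(st$g0, 1, 4), "does not admit")
})

test_that("fusion concatenates two contigs with the published factors", {
  st <- worked_states()
  expect_factors(st$fu, list(c(-10, -8), c(-4, -9), c(9, 7), c(-5, 10)))
  expect_true(perm_equal(st$g2$perm, perm_parse(
    "(7,1,4,-5,6,8)(-8,-6,5,-4,-1,-7)(9,10)(-10,-9)(11,3,2,12)(-12,-2,-3,-11)",
    elems = E12)))
  expect_identical(length(blockorder:::gene_strands(st$g2)), 4L)  # one fewer contig
  expect_error(build_fusion(st$g1, 4, 8), "characters")
  expect_error(build_fusion(st$g1, -5, 8), "same contig")
})

test_that("alternative fusion uses a mediating 3' cap and still fuses", {
  st <- worked_states()
  expect_factors(st$af, list(c(-6, -11), c(-6, -2), c(12, 8), c(3, 8)))
  expect_true(perm_equal(st$g3$perm, perm_parse(
    "(7,1,4,-5,6,3,2,8)(-8,-2,-3,-6,5,-4,-1,-7)(9,10)(-10,-9)(11,12)(-12,-11)",
    elems = E12)))
  expect_identical(length(blockorder:::gene_strands(st$g3)), 2L)
  expect_error(build_alt_fusion(st$g2, -5, 12, 8), "characters")
})

test_that("reversal reverses exactly one signed segment", {
  st <- worked_states()
  expect_factors(st$rv, list(c(5, -5), c(-4, 6)))
  expect_identical(uncap_assembly(st$g3), c(1L, 4L, -5L, 6L, 3L, 2L))
  expect_identical(uncap_assembly(st$g4), c(1L, 4L, 5L, 6L, 3L, 2L))
  expect_error(build_reversal(st$g3, 1, 4), "same strand")
  # with a fixed orientation, flipping a single gene costs one reversal;
  # the ordering solver is free to flip the whole one-contig draft, so
  # its distance is 0
  expect_identical(weighted_rearrangement_distance(-1L, 1L), 1L)
  expect_identical(block_order(draft_genome(list(-1L)), reference_genome(1L))$distance, 0L)
})

test_that("the residual quotient acts as a block-interchange completing the sort", {
  st <- worked_states()
  # residual (2,4)(-1,-3)(3,8)(-2,-6) exchanged as one block-interchange
  expect_true(perm_equal(st$prod4, perm_parse("(2,4)(-1,-3)(3,8)(-2,-6)", elems = E12)))
  ev <- build_block_interchange(st$g4, 4, 3, 2, 8)
  r <- apply_event(st$g4, st$prod4, ev)
  expect_true(perm_equal(r$genome$perm, cap_reference(worked_ref(), 3)$perm))
  expect_true(perm_is_identity(r$prod))
  expect_error(build_block_interchange(st$g4, 2, 3, 4, 8), "order x, u, y, v")
})

test_that("exchanging two segments twice restores the genome", {
  g <- cap_draft(draft_genome(list(c(1, 2, 3, 4))))
  ev <- build_block_interchange(g, 1, 2, 3, 4)
  g2 <- apply_event(g, perm_id(g$elems), ev)$genome
  expect_true(blockorder:::strand_paired(g2$perm))
  expect_false(perm_equal(g2$perm, g$perm))
  # search the re-exchange on the new genome
  restored <- FALSE
  genes <- c(1:4, -(1:4))
  for (x in genes) for (u in genes) for (y in genes) for (v in genes) {
    q <- c(x, u, y, v)
    if (anyDuplicated(q)) next
    ok <- tryCatch(perm_ordered_in_cycle(q, g2$perm), error = function(e) FALSE)
    if (!ok) next
    ev2 <- build_block_interchange(g2, x, u, y, v)
    g3 <- apply_event(g2, perm_id(g$elems), ev2)$genome
    if (perm_equal(g3$perm, g$perm)) { restored <- TRUE; break }
  }
  expect_true(restored)
})

test_that("incremental quotient updates equal from-scratch recomputation", {
  st <- worked_states()
  sg <- cap_reference(worked_ref(), 3)
  for (stage in list(list(st$g1, st$prod1), list(st$g2, st$prod2),
                     list(st$g3, st$prod3), list(st$g4, st$prod4))) {
    expect_true(perm_equal(
      perm_compose(sg$perm, perm_inverse(stage[[1]]$perm)), stage[[2]]))
  }
  # identity-factored event changes nothing
  noop <- blockorder:::new_event("cap_exchange", c(x = 1L, y = 2L),
                                 list(c(1L, 1L), c(2L, 2L)), 0L)
  r <- apply_event(st$g1, st$prod1, noop)
  expect_true(perm_equal(r$genome$perm, st$g1$perm))
  expect_true(perm_equal(r$prod, st$prod1))
})

test_that("events preserve strand pairing, admissibility and mate cycles", {
  st <- worked_states()
  for (g in list(st$g1, st$g2, st$g3, st$g4)) {
    expect_true(blockorder:::strand_paired(g$perm))
    expect_true(blockorder:::admissible(g$perm))
  }
  # mate-cycle pairing of every intermediate quotient
  for (stage in list(list(st$g1, st$prod1), list(st$g2, st$prod2),
                     list(st$g3, st$prod3), list(st$g4, st$prod4))) {
    g <- stage[[1]]; prod <- stage[[2]]
    cyc <- perm_cycles(prod)
    keys <- vapply(cyc, paste, character(1), collapse = ",")
    for (a in cyc) {
      mate <- blockorder:::rotate_cycle_canonical(perm_apply(g$perm, -rev(a)))
      expect_true(paste(mate, collapse = ",") %in% keys)
    }
  }
})
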