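# Rearrangement events as products of 2-cycles.
#
# Every event is a short product of 2-cycles multiplied onto the capped
# genome permutation: 2 factors for a reversal, 4 for a block-interchange,
# fusion or cap exchange.  Factors are stored in application order (the
# rightmost printed factor first), so applying an event means composing
# factors[[1]], then factors[[2]], ... onto the current permutation.

new_event <- function(kind, anchors, factors, weight) {
  structure(list(kind = kind, anchors = anchors, factors = factors,
                 weight = as.integer(weight)),
            class = "rearr_event")
}

#' @export
print.rearr_event <- function(x, ...) {
  cat("<", x$kind, "> weight ", x$weight, "  anchors: ",
      paste(names(x$anchors), "=", x$anchors, collapse = ", "),
      "\n  factors: ", event_factor_string(x), "\n", sep = "")
  invisible(x)
}

event_factor_string <- function(ev) {
  paste(vapply(rev(ev$factors),
               function(f) paste0("(", paste(f, collapse = ","), ")"),
               character(1)), collapse = "")
}

#' Composed permutation of an event's 2-cycle factors
#' @param ev A `rearr_event`.
#' @param elems Ground set over which to realize the product.
#' @return A `perm`: the product of the event's factors.
#' @export
event_product <- function(ev, elems) {
  p <- perm_id(elems)
  for (f in ev$factors) {
    if (f[1] != f[2]) p <- perm_compose(perm(list(f), elems = elems), p)
  }
  p
}

# pi_hat Gammahat, evaluated on demand: x -> pi_hat(-x)
pg <- function(g, x) perm_apply(g$perm, -as.integer(x))

# CEpair: character pairs that admit a cap exchange
CE_PAIRS <- c("C3.C3", "C3.N3", "T.T", "T.N3", "N3.N3")

is_cepair <- function(cx, cy) {
  paste(cx, cy, sep = ".") %in% CE_PAIRS || paste(cy, cx, sep = ".") %in% CE_PAIRS
}

# x and y belong to one contig iff they share a strand cycle of pi_hat,
# either directly or across the two complementary strands
same_contig <- function(g, x, y) {
  if (x == y || x == -y) return(TRUE)
  perm_ordered_in_cycle(c(x, y), g$perm) ||
    perm_ordered_in_cycle(c(x, -y), g$perm)
}

# shared 4-factor translocation layout: (x,y), (5cap x, 5cap y),
# (piG(y), piG(x)), (piG(5cap y), piG(5cap x)), applied in that order
translocation_factors <- function(g, x, y) {
  fx <- five_cap(x, g); fy <- five_cap(y, g)
  list(c(x, y), c(fx, fy), c(pg(g, y), pg(g, x)), c(pg(g, fy), pg(g, fx)))
}

#' Build a cap-exchange event
#'
#' Swaps the caps of the contigs containing `x` and `y` while leaving the
#' uncapped genome unchanged.  The character pair of `(x, y)` must belong
#' to the cap-exchange set \{(C3,C3), (C3,N3), (T,T), (T,N3), (N3,N3)\},
#' and `x` and `y` must lie in different contigs of the capped genome.
#'
#' @param g A `capped_genome`.
#' @param x,y Anchor elements.
#' @return A `rearr_event` of weight 0.
#' @export
build_cap_exchange <- function(g, x, y) {
  x <- as.integer(x); y <- as.integer(y)
  cx <- genome_char(x, g); cy <- genome_char(y, g)
  if (!is_cepair(cx, cy)) {
    stop("character pair (", cx, ",", cy, ") does not admit a cap exchange")
  }
  # x and y must lie in different strand cycles (possibly the two strands
  # of one contig: that exchange flips the contig's reading relative to
  # its caps, still leaving the underlying molecule unchanged)
  if (x == y || perm_ordered_in_cycle(c(x, y), g$perm)) {
    stop("cap-exchange anchors lie on the same strand")
  }
  new_event("cap_exchange", c(x = x, y = y), translocation_factors(g, x, y), 0L)
}

#' Build a fusion event
#'
#' Concatenates the contig containing `y` (a 3' cap) onto the contig
#' containing `x` (a tail).  Requires `char(x) = T`, `char(y) = C3`, and
#' `x`, `y` in different contigs of the capped genome.
#'
#' @inheritParams build_cap_exchange
#' @return A `rearr_event` of weight 0.
#' @export
build_fusion <- function(g, x, y) {
  x <- as.integer(x); y <- as.integer(y)
  cx <- genome_char(x, g); cy <- genome_char(y, g)
  if (!(cx == "T" && cy == "C3")) {
    stop("fusion needs characters (T, C3), got (", cx, ",", cy, ")")
  }
  if (same_contig(g, x, y)) stop("fusion anchors lie in the same contig")
  new_event("fusion", c(x = x, y = y), translocation_factors(g, x, y), 0L)
}

#' Build an alternative fusion event
#'
#' Used when the tail `x` and the 3' cap `y` already lie in the same
#' contig strand: a 3' cap `z` of a different gene-bearing contig mediates
#' the concatenation.  The net effect on the uncapped genome is still one
#' fusion (a fusion followed by a cap exchange in the capped space).
#'
#' @inheritParams build_cap_exchange
#' @param z A 3' cap of a different gene-bearing contig, `z != y`.
#' @return A `rearr_event` of weight 0.
#' @export
build_alt_fusion <- function(g, x, y, z) {
  x <- as.integer(x); y <- as.integer(y); z <- as.integer(z)
  cx <- genome_char(x, g); cy <- genome_char(y, g); cz <- genome_char(z, g)
  if (!(cx == "T" && cy == "C3")) {
    stop("alternative fusion needs characters (T, C3), got (", cx, ",", cy, ")")
  }
  if (!perm_ordered_in_cycle(c(x, y), g$perm)) {
    stop("alternative fusion requires x and y in one contig strand")
  }
  if (cz != "C3" || z == y) stop("z must be a 3' cap of a different gene-bearing contig")
  if (same_contig(g, x, z)) stop("z must belong to a different contig than x")
  factors <- list(c(x, z), c(y, z), c(pg(g, z), pg(g, y)), c(pg(g, z), pg(g, x)))
  new_event("fusion_alt", c(x = x, y = y, z = z), factors, 0L)
}

#' Build a reversal event
#'
#' Requires `x` and `y` on different strands of the capped genome
#' (`(x,y)` does not divide it); the event reverses and strand-swaps one
#' contiguous segment.
#'
#' @inheritParams build_cap_exchange
#' @return A `rearr_event` of weight 1.
#' @export
build_reversal <- function(g, x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (perm_ordered_in_cycle(c(x, y), g$perm)) {
    stop("reversal anchors lie on the same strand")
  }
  new_event("reversal", c(x = x, y = y),
            list(c(x, y), c(pg(g, y), pg(g, x))), 1L)
}

#' Build a block-interchange event
#'
#' Requires `x, u, y, v` on one strand of the capped genome in that
#' cyclic order; the event exchanges the two segments delimited by
#' `(x, y)` and `(u, v)`.
#'
#' @inheritParams build_cap_exchange
#' @param u,v Second anchor pair.
#' @return A `rearr_event` of weight 2.
#' @export
build_block_interchange <- function(g, x, u, y, v) {
  x <- as.integer(x); u <- as.integer(u); y <- as.integer(y); v <- as.integer(v)
  if (!perm_ordered_in_cycle(c(x, u, y, v), g$perm)) {
    stop("block-interchange anchors must appear on one strand in the order x, u, y, v")
  }
  new_event("block_interchange", c(x = x, u = u, y = y, v = v),
            list(c(x, y), c(u, v), c(pg(g, y), pg(g, x)), c(pg(g, v), pg(g, u))), 2L)
}

#' Apply an event to a capped genome and the tracked quotient
#'
#' Multiplies the event's factors onto the capped permutation and updates
#' the quotient permutation (the running `sigma_hat pi_hat^-1`) by the
#' event's inverse, exactly as the incremental update rules of the
#' ordering algorithm prescribe.
#'
#' @param g A `capped_genome` the event was built against.
#' @param prod A `perm`: the current quotient `sigma_hat pi_hat^-1`.
#' @param ev A `rearr_event`.
#' @return A list with elements `genome` (new `capped_genome`) and `prod`
#'   (new quotient `perm`).
#' @export
apply_event <- function(g, prod, ev) {
  evp <- event_product(ev, g$elems)
  newp <- perm_compose(evp, g$perm)
  newprod <- perm_compose(prod, perm_inverse(evp))
  g$perm <- newp
  list(genome = g, prod = newprod)
}
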