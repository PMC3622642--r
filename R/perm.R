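#' Permutations over finite signed-integer ground sets
#'
#' A `perm` object is a bijection of a finite set of nonzero integers onto
#' itself, stored as a dense mapping and manipulated through its
#' disjoint-cycle decomposition.  The ground set is always explicit: the
#' norm of a permutation depends on the size of the set it acts on, not
#' just on its support.
#'
#' @param cycles A list of integer vectors, each a cycle `(a1, ..., ak)`
#'   meaning `a1 -> a2 -> ... -> ak -> a1`.  Cycles must be disjoint.
#'   A single vector is taken as one cycle.
#' @param elems Integer vector: the ground set.  Defaults to the union of
#'   the cycle supports.
#' @return A `perm` object.
#' @examples
#' a <- perm(c(1, 3), elems = 1:4)
#' b <- perm(c(1, 2, 3, 4))
#' perm_format(perm_compose(a, b))  # "(1,2)(3,4)"
#' @export
perm <- function(cycles, elems = NULL) {
  if (is.numeric(cycles)) cycles <- list(as.integer(cycles))
  cycles <- lapply(cycles, as.integer)
  supp <- unlist(cycles)
  if (anyDuplicated(supp)) stop("cycles are not disjoint")
  if (any(supp == 0L)) stop("ground set elements must be nonzero")
  if (is.null(elems)) elems <- supp
  elems <- sort(unique(as.integer(elems)))
  if (any(elems == 0L)) stop("ground set elements must be nonzero")
  if (!all(supp %in% elems)) stop("cycle elements outside the ground set")
  map <- elems
  for (cy in cycles) {
    if (length(cy) < 2L) next
    map[match(cy, elems)] <- cy[c(2:length(cy), 1L)]
  }
  new_perm(elems, map)
}

new_perm <- function(elems, map) {
  structure(list(elems = elems, map = as.integer(map)), class = "perm")
}

#' Identity permutation on a ground set
#' @param elems Integer vector, the ground set.
#' @return A `perm` fixing every element.
#' @export
perm_id <- function(elems) {
  elems <- sort(unique(as.integer(elems)))
  if (any(elems == 0L)) stop("ground set elements must be nonzero")
  new_perm(elems, elems)
}

perm_check_same_ground <- function(a, b) {
  if (!identical(a$elems, b$elems)) stop("permutations act on different ground sets")
}

#' Apply a permutation to elements
#' @param p A `perm`.
#' @param x Integer vector of elements of the ground set.
#' @return `p(x)`, element-wise.
#' @export
perm_apply <- function(p, x) {
  i <- match(as.integer(x), p$elems)
  if (anyNA(i)) stop("element not in ground set: ", paste(x[is.na(i)], collapse = ", "))
  p$map[i]
}

#' Preimage under a permutation
#' @inheritParams perm_apply
#' @return `p^-1(x)`, element-wise.
#' @export
perm_preimage <- function(p, x) {
  i <- match(as.integer(x), p$map)
  if (anyNA(i)) stop("element not in ground set: ", paste(x[is.na(i)], collapse = ", "))
  p$elems[i]
}

#' Compose permutations
#'
#' `perm_compose(a, b)` is the product `ab` acting as `ab(x) = a(b(x))`;
#' additional arguments compose left to right, so
#' `perm_compose(a, b, c) = abc`.
#'
#' @param ... `perm` objects over one common ground set.
#' @return The composed `perm`.
#' @export
perm_compose <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "perm")) ps <- ps[[1]]
  stopifnot(length(ps) >= 1L)
  out <- ps[[length(ps)]]
  if (length(ps) > 1L) {
    for (k in (length(ps) - 1L):1L) {
      a <- ps[[k]]
      perm_check_same_ground(a, out)
      out <- new_perm(a$elems, a$map[match(out$map, a$elems)])
    }
  }
  out
}

#' Invert a permutation
#' @param p A `perm`.
#' @return The inverse permutation.
#' @export
perm_inverse <- function(p) {
  new_perm(p$elems, p$elems[match(p$elems, p$map)])
}

#' Conjugate one permutation by another
#'
#' The conjugation of `b` by `a` is `a b a^-1`, i.e. `b` with every cycle
#' element `x` relabelled to `a(x)`.
#'
#' @param a,b `perm` objects over one common ground set.
#' @return `a b a^-1`.
#' @export
perm_conjugate <- function(a, b) {
  perm_check_same_ground(a, b)
  # relabel: image of a(x) is a(b(x))
  map <- a$elems
  map[match(perm_apply(a, b$elems), a$elems)] <- perm_apply(a, b$map)
  new_perm(a$elems, map)
}

#' Disjoint-cycle decomposition
#'
#' Cycles are returned in canonical form: each cycle is rotated so that it
#' starts at its element of smallest absolute value (a positive element
#' wins a tie against its negation), and cycles are sorted by that leading
#' element, smaller absolute values first.
#'
#' @param p A `perm`.
#' @param all If `TRUE`, include the trivial 1-cycles (fixed points).
#' @return A list of integer vectors.
#' @export
perm_cycles <- function(p, all = FALSE) {
  elems <- p$elems
  succ <- match(p$map, elems)  # successor position of each position
  n <- length(elems)
  seen <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    if (succ[i] == i) {
      seen[i] <- TRUE
      if (all) out[[length(out) + 1L]] <- elems[i]
      next
    }
    pos <- integer(0)
    j <- i
    repeat {
      seen[j] <- TRUE
      pos[length(pos) + 1L] <- j
      j <- succ[j]
      if (j == i) break
    }
    out[[length(out) + 1L]] <- elems[pos]
  }
  out <- lapply(out, rotate_cycle_canonical)
  if (length(out) > 1L) {
    leaders <- vapply(out, `[[`, integer(1), 1L)
    out <- out[order(2L * abs(leaders) + (leaders < 0L))]
  }
  out
}

rotate_cycle_canonical <- function(cy) {
  k <- which.min(2L * abs(cy) + (cy < 0L))
  if (k > 1L) cy <- c(cy[k:length(cy)], cy[seq_len(k - 1L)])
  cy
}

#' Number of disjoint cycles, including implicit 1-cycles
#' @param p A `perm`.
#' @return Integer count `n_c(p)`.
#' @export
perm_nc <- function(p) {
  succ <- match(p$map, p$elems)
  seen <- logical(length(succ))
  cnt <- 0L
  for (i in seq_along(succ)) {
    if (seen[i]) next
    cnt <- cnt + 1L
    j <- i
    while (!seen[j]) {
      seen[j] <- TRUE
      j <- succ[j]
    }
  }
  cnt
}

#' Norm of a permutation
#'
#' `||p|| = |E| - n_c(p)`: the minimum number of 2-cycles (transpositions)
#' whose product is `p`.
#'
#' @param p A `perm`.
#' @return Non-negative integer.
#' @export
perm_norm <- function(p) {
  length(p$elems) - perm_nc(p)
}

#' Divisibility of permutations
#'
#' `a` divides `b` iff `||b a^-1|| = ||b|| - ||a||`.  For a cycle
#' `(a1, ..., ak)`, divisibility of `b` is equivalent to the `ai`
#' appearing in one cycle of `b` in that cyclic order.
#'
#' @param a,b `perm` objects over one common ground set.
#' @return Logical.
#' @export
perm_divides <- function(a, b) {
  perm_check_same_ground(a, b)
  perm_norm(perm_compose(b, perm_inverse(a))) == perm_norm(b) - perm_norm(a)
}

#' Test cyclic order of elements within a cycle
#'
#' True iff all elements of `tuple` lie in a single cycle of `p` and occur
#' there in the given cyclic order; equivalently, the cycle
#' `(tuple[1], ..., tuple[k])` divides `p`.
#'
#' @param tuple Integer vector of distinct ground-set elements.
#' @param p A `perm`.
#' @return Logical.
#' @export
perm_ordered_in_cycle <- function(tuple, p) {
  tuple <- as.integer(tuple)
  if (anyDuplicated(tuple)) stop("tuple elements must be distinct")
  if (length(tuple) < 2L) return(TRUE)
  # walk the cycle containing tuple[1], recording the visit rank of each
  # tuple element; all must be present and their ranks cyclically increasing
  start <- match(tuple[1], p$elems)
  if (is.na(start)) stop("element not in ground set: ", tuple[1])
  ti <- match(tuple, p$elems)
  if (anyNA(ti)) stop("element not in ground set: ", paste(tuple[is.na(ti)], collapse = ", "))
  succ <- match(p$map, p$elems)
  rank <- rep(NA_integer_, length(tuple))
  rank[1] <- 0L
  j <- succ[start]
  step <- 1L
  while (j != start) {
    hit <- match(j, ti)
    if (!is.na(hit)) rank[hit] <- step
    j <- succ[j]
    step <- step + 1L
  }
  !anyNA(rank) && !is.unsorted(rank)
}

#' Render a permutation in cycle notation
#'
#' One-cycles are omitted, matching the usual printed convention; the
#' identity renders as `"1"`.
#'
#' @param p A `perm`.
#' @return A character scalar such as `"(2,4)(-1,-3)"`.
#' @export
perm_format <- function(p) {
  cyc <- perm_cycles(p)
  if (length(cyc) == 0L) return("1")
  paste(vapply(cyc, function(cy) paste0("(", paste(cy, collapse = ","), ")"),
               character(1)), collapse = "")
}

#' Parse cycle notation
#'
#' Inverse of [perm_format()]: parses products such as
#' `"(2,4)(-1,-3)(5,-5,10,8)"`.  The printed cycles must be disjoint.
#'
#' @param text Character scalar in cycle notation; `"1"` is the identity.
#' @param elems Ground set; defaults to the support of the parsed cycles.
#' @return A `perm`.
#' @export
perm_parse <- function(text, elems = NULL) {
  text <- gsub("[[:space:]−]", "", text)
  text <- gsub("−", "-", text)
  if (text == "1" || text == "") {
    if (is.null(elems)) stop("parsing the identity requires an explicit ground set")
    return(perm_id(elems))
  }
  if (!grepl("^(\\((-?[0-9]+)(,-?[0-9]+)*\\))+$", text)) {
    stop("malformed cycle notation: ", text)
  }
  bodies <- regmatches(text, gregexpr("\\(([^)]*)\\)", text))[[1]]
  cycles <- lapply(bodies, function(b) {
    as.integer(strsplit(gsub("[()]", "", b), ",")[[1]])
  })
  perm(cycles, elems = elems)
}

#' Test two permutations for equality
#' @param a,b `perm` objects.
#' @return Logical: same ground set and same mapping.
#' @export
perm_equal <- function(a, b) {
  identical(a$elems, b$elems) && identical(a$map, b$map)
}

#' Is a permutation the identity?
#' @param p A `perm`.
#' @return Logical.
#' @export
perm_is_identity <- function(p) {
  identical(p$map, p$elems)
}

#' @export
print.perm <- function(x, ...) {
  cat("<perm on", length(x$elems), "elements>", perm_format(x), "\n")
  invisible(x)
}

# Cycles in the solver's deterministic scan order: positive leaders
# ascending first, then negative leaders by ascending absolute value.
# This ordering (rather than plain smallest-|leader|-first) is what makes
# the solver reproduce the published worked trace event by event.
scan_cycles <- function(p) {
  cyc <- perm_cycles(p)
  if (length(cyc) <= 1L) return(cyc)
  leaders <- vapply(cyc, `[[`, integer(1), 1L)
  cyc[order(abs(leaders) + (leaders < 0L) * (max(abs(leaders)) + 1L))]
}

# Positive-first total order used for deterministic candidate choices.
positive_first_order <- function(x) {
  if (!length(x)) return(integer(0))
  order(abs(x) + (x < 0L) * (max(abs(x)) + 1L))
}
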