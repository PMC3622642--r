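# Independent brute-force certification of optimality.
#
# Works purely on signed gene sequences: signed reversals (weight 1) and
# block-interchanges (weight 2) generate a move graph whose weighted
# shortest paths are found by uniform-cost search.  Nothing here touches
# the permutation-group solver, so agreement between the two is a real
# cross-check.

ORACLE_N_BOUND <- 8L

# move templates for sequences of length n: each move is a position
# permutation plus a sign mask; applying a move is s[idx] * sgn
moves_cache <- new.env(parent = emptyenv())

seqi <- function(a, b) if (b < a) integer(0) else a:b

moves_for_n <- function(n) {
  key <- as.character(n)
  if (!is.null(moves_cache[[key]])) return(moves_cache[[key]])
  moves <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- seq_len(n)
      idx[i:j] <- rev(i:j)
      sgn <- rep(1L, n)
      sgn[i:j] <- -1L
      moves[[length(moves) + 1L]] <- list(idx = idx, sgn = sgn, w = 1L)
    }
  }
  # two non-overlapping segments [i1..j1], [i2..j2] with j1 < i2 exchanged
  for (i1 in seq_len(n)) for (j1 in i1:n) for (i2 in seqi(j1 + 1L, n)) for (j2 in i2:n) {
    idx <- c(seqi(1L, i1 - 1L), i2:j2, seqi(j1 + 1L, i2 - 1L), i1:j1, seqi(j2 + 1L, n))
    moves[[length(moves) + 1L]] <- list(idx = idx, sgn = rep(1L, n), w = 2L)
  }
  moves_cache[[key]] <- moves
  moves
}

#' Neighboring sequences under one weighted rearrangement
#'
#' All signed reversals (weight 1) and block-interchanges of two
#' non-overlapping segments (weight 2, adjacent segments -- i.e.
#' transpositions -- included) applicable to a signed gene sequence.
#'
#' @param state Signed integer vector (each absolute value once).
#' @return A list with elements `state` and `weight` per move.
#' @export
rearrangement_neighbors <- function(state) {
  n <- length(state)
  if (n > ORACLE_N_BOUND) stop("oracle is limited to n <= ", ORACLE_N_BOUND)
  lapply(moves_for_n(n), function(mv) {
    list(state = state[mv$idx] * mv$sgn, weight = mv$w)
  })
}

state_key <- function(s) paste(s, collapse = ",")

# uniform-cost search from `start` over the move graph; stops when
# `goal_key` is settled (or never, if NULL, in which case the whole
# reachable ball up to `cap` is settled) and returns the distance env
ucs <- function(start, goal_key = NULL, cap = Inf) {
  n <- length(start)
  moves <- moves_for_n(n)
  dist <- new.env(hash = TRUE, parent = emptyenv())
  k0 <- state_key(start)
  assign(k0, 0L, envir = dist)
  buckets <- list()
  buckets[[1L]] <- list(start)  # bucket c+1 holds states queued at cost c
  cost <- 0L
  while (cost <= cap) {
    b <- if (cost + 1L <= length(buckets)) buckets[[cost + 1L]] else NULL
    if (is.null(b) || !length(b)) {
      cost <- cost + 1L
      if (cost + 1L > length(buckets)) break
      next
    }
    buckets[[cost + 1L]] <- list()
    for (s in b) {
      k <- state_key(s)
      if (get(k, envir = dist) != cost) next  # stale queue entry
      if (!is.null(goal_key) && k == goal_key) return(dist)
      for (mv in moves) {
        ns <- s[mv$idx] * mv$sgn
        nk <- state_key(ns)
        nc <- cost + mv$w
        old <- get0(nk, envir = dist, ifnotfound = NA_integer_)
        if (is.na(old) || nc < old) {
          assign(nk, nc, envir = dist)
          while (length(buckets) < nc + 1L) buckets[length(buckets) + 1L] <- list(list())
          buckets[[nc + 1L]][[length(buckets[[nc + 1L]]) + 1L]] <- ns
        }
      }
    }
  }
  dist
}

# full distance tables from the identity, cached per n (n <= 6): one
# exhaustive uniform-cost search serves every query at that size because
# position moves commute with gene relabelling
table_cache <- new.env(parent = emptyenv())

identity_distance_table <- function(n) {
  key <- as.character(n)
  if (is.null(table_cache[[key]])) {
    table_cache[[key]] <- ucs(seq_len(n), goal_key = NULL, cap = Inf)
  }
  table_cache[[key]]
}

relabel_to_identity <- function(source, target) {
  j <- match(abs(source), abs(target))
  if (anyNA(j) || length(source) != length(target)) {
    stop("source and target are not over the same gene set")
  }
  as.integer(j * sign(source) * sign(target[j]))
}

#' Minimum weighted rearrangement distance by uniform-cost search
#'
#' Transforms `source` into `target` by signed reversals (weight 1) and
#' block-interchanges (weight 2) of minimum total weight.  Independent of
#' the permutation-group solver; exact but exponential, for small `n`
#' only.
#'
#' @param source,target Signed gene sequences over the same gene set.
#' @param cap Error if the distance exceeds this bound.
#' @return Integer distance.
#' @export
weighted_rearrangement_distance <- function(source, target, cap = Inf) {
  n <- length(source)
  if (n > ORACLE_N_BOUND) stop("oracle is limited to n <= ", ORACLE_N_BOUND)
  rel <- relabel_to_identity(source, target)
  if (n <= 6L) {
    d <- get(state_key(rel), envir = identity_distance_table(n))
  } else {
    finite_cap <- if (is.finite(cap)) cap else 3L * n
    dist <- ucs(rel, goal_key = state_key(seq_len(n)), cap = finite_cap)
    k <- state_key(seq_len(n))
    if (!exists(k, envir = dist)) stop("distance exceeds cap ", finite_cap)
    d <- get(k, envir = dist)
  }
  if (d > cap) stop("distance ", d, " exceeds cap ", cap)
  d
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Exhaustive optimal ordering of a draft genome
#'
#' Enumerates every ordering and orientation of the contigs, concatenates
#' each into a signed sequence, and measures its weighted rearrangement
#' distance to the reference by uniform-cost search.  Returns the minimum
#' and every ordering attaining it.  This is the optimality oracle for
#' the exact solver; tractable only for `m <= 4`, `n <= 8`.
#'
#' @inheritParams block_order
#' @return A list with `distance` (integer) and `assemblies` (list of
#'   optimal induced sequences) and `orderings` (list of data frames with
#'   contig index and orientation).
#' @export
brute_force_order <- function(draft, ref) {
  if (!inherits(draft, "draft_genome")) draft <- draft_genome(draft)
  if (!inherits(ref, "reference_genome")) ref <- reference_genome(ref)
  if (draft$m > 4L || draft$n > ORACLE_N_BOUND) {
    stop("brute force is limited to m <= 4 and n <= ", ORACLE_N_BOUND)
  }
  best <- Inf
  assemblies <- list()
  orderings <- list()
  for (ord in all_permutations(seq_len(draft$m))) {
    for (mask in 0:(2L^draft$m - 1L)) {
      flips <- as.integer(bitwAnd(bitwShiftR(mask, seq_len(draft$m) - 1L), 1L))
      seqs <- lapply(seq_len(draft$m), function(k) {
        b <- draft$blocks[[ord[k]]]
        if (flips[k]) -rev(b) else b
      })
      induced <- unlist(seqs)
      d <- weighted_rearrangement_distance(induced, ref$order)
      if (d < best) {
        best <- d
        assemblies <- list(induced)
        orderings <- list(data.frame(index = ord, orientation = 1L - 2L * flips))
      } else if (d == best) {
        assemblies[[length(assemblies) + 1L]] <- induced
        orderings[[length(orderings) + 1L]] <- data.frame(index = ord,
                                                          orientation = 1L - 2L * flips)
      }
    }
  }
  list(distance = as.integer(best), assemblies = assemblies, orderings = orderings)
}
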