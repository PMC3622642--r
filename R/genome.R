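#' Construct and validate a draft genome
#'
#' A draft (partially assembled) genome is an unordered collection of
#' contigs; each contig is an ordered list of signed gene/marker IDs, and
#' the absolute gene values across all contigs must cover `1..n` exactly
#' once.
#'
#' @param blocks A list of integer vectors (one per contig), or a single
#'   vector for a one-contig draft.
#' @param n Gene count; defaults to the number of genes found.
#' @param names Optional character vector of contig names.
#' @return A `draft_genome` object with fields `blocks`, `n`, `m`.
#' @examples
#' draft_genome(list(c(1, 4), c(-5, 6), c(3, 2)))
#' @export
draft_genome <- function(blocks, n = NULL, names = NULL) {
  if (is.numeric(blocks)) blocks <- list(blocks)
  blocks <- lapply(blocks, as.integer)
  if (length(blocks) < 1L) stop("a draft genome needs at least one contig")
  if (any(vapply(blocks, length, integer(1)) == 0L)) stop("empty contig")
  genes <- unlist(blocks)
  if (any(genes == 0L)) stop("gene ID 0 is not allowed")
  dup <- unique(abs(genes)[duplicated(abs(genes))])
  if (length(dup)) stop("duplicated gene ID: ", paste(dup, collapse = ", "))
  if (is.null(n)) n <- length(genes)
  n <- as.integer(n)
  missing <- setdiff(seq_len(n), abs(genes))
  if (length(missing)) stop("missing gene ID: ", paste(missing, collapse = ", "))
  extra <- setdiff(abs(genes), seq_len(n))
  if (length(extra)) stop("gene ID out of range 1..n: ", paste(extra, collapse = ", "))
  if (is.null(names)) names <- paste0("B", seq_along(blocks))
  structure(list(blocks = blocks, n = n, m = length(blocks), names = names),
            class = "draft_genome")
}

#' Construct and validate a reference genome
#'
#' @param order Integer vector: the complete signed gene order.
#' @return A `reference_genome` object with fields `order`, `n`.
#' @export
reference_genome <- function(order) {
  g <- draft_genome(list(order))
  structure(list(order = g$blocks[[1]], n = g$n), class = "reference_genome")
}

#' @export
print.draft_genome <- function(x, ...) {
  cat("Draft genome:", x$m, "contig(s),", x$n, "genes\n")
  for (i in seq_len(x$m)) {
    cat(" ", x$names[i], ": [", paste(x$blocks[[i]], collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("Reference genome:", x$n, "genes: (",
      paste(x$order, collapse = ", "), ")\n")
  invisible(x)
}

#' Double-strand permutation representation of a draft genome
#'
#' Each contig `[b1, ..., bk]` contributes the strand cycle
#' `(b1, ..., bk)` and its reverse complement `(-bk, ..., -b1)` over the
#' ground set `{-n..-1, 1..n}`.
#'
#' @param g A `draft_genome`.
#' @return A `perm` over `{±1..±n}`.
#' @export
strand_perm <- function(g) {
  stopifnot(inherits(g, "draft_genome"))
  elems <- setdiff(-g$n:g$n, 0L)
  cycles <- list()
  for (b in g$blocks) {
    if (length(b) > 1L) {
      cycles[[length(cycles) + 1L]] <- b
      cycles[[length(cycles) + 1L]] <- -rev(b)
    }
  }
  perm(cycles, elems = elems)
}

# cap identities for n genes, m contigs: contig i gets 5' caps
# {n+2i-1, -(n+2i)} and 3' caps {n+2i, -(n+2i-1)} at capping time.  These
# role sets are invariant under every event the solver applies (cap
# exchanges move caps between contigs but never turn a 5' cap into a 3'
# cap), so they are stored once on the capped genome.
cap_roles <- function(n, m) {
  i <- seq_len(m)
  list(five = c(n + 2L * i - 1L, -(n + 2L * i)),
       three = c(n + 2L * i, -(n + 2L * i - 1L)))
}

new_capped_genome <- function(n, m, p) {
  roles <- cap_roles(n, m)
  structure(list(n = n, m = m, perm = p,
                 fivecaps = roles$five, threecaps = roles$three,
                 elems = p$elems),
            class = "capped_genome")
}

#' Cap the contigs of a draft genome
#'
#' Contig `i` (in input order) is augmented with the 5' cap
#' `c(2(i-1)) = n + 2i - 1` and the 3' cap `c(2(i-1)+1) = n + 2i` on its
#' forward strand; the reverse strand carries the negated caps.  The
#' result is a permutation over the extended ground set
#' `{±1 .. ±(n+2m)}`.
#'
#' @param g A `draft_genome`.
#' @return A `capped_genome` with fields `n`, `m`, `perm`, `fivecaps`,
#'   `threecaps`.
#' @examples
#' g <- draft_genome(list(c(1, 4), c(-5, 6), c(3, 2)))
#' perm_format(cap_draft(g)$perm)
#' @export
cap_draft <- function(g) {
  stopifnot(inherits(g, "draft_genome"))
  n <- g$n; m <- g$m
  elems <- setdiff(-(n + 2L * m):(n + 2L * m), 0L)
  cycles <- list()
  for (i in seq_len(m)) {
    b <- g$blocks[[i]]
    c5 <- n + 2L * i - 1L
    c3 <- n + 2L * i
    cycles[[length(cycles) + 1L]] <- c(c5, b, c3)
    cycles[[length(cycles) + 1L]] <- c(-c3, -rev(b), -c5)
  }
  new_capped_genome(n, m, perm(cycles, elems = elems))
}

#' Cap a reference genome against an m-contig draft
#'
#' The reference order becomes the first capped contig (caps `n+1`,
#' `n+2`); `m - 1` null contigs (caps only, no genes) are appended so
#' that both capped genomes use the same cap set.
#'
#' @param r A `reference_genome`.
#' @param m Contig count of the draft genome.
#' @return A `capped_genome`.
#' @export
cap_reference <- function(r, m) {
  stopifnot(inherits(r, "reference_genome"), m >= 1L)
  n <- r$n; m <- as.integer(m)
  elems <- setdiff(-(n + 2L * m):(n + 2L * m), 0L)
  cycles <- list(c(n + 1L, r$order, n + 2L),
                 c(-(n + 2L), -rev(r$order), -(n + 1L)))
  if (m > 1L) {
    for (i in 2:m) {
      c5 <- n + 2L * i - 1L
      c3 <- n + 2L * i
      cycles[[length(cycles) + 1L]] <- c(c5, c3)
      cycles[[length(cycles) + 1L]] <- c(-c3, -c5)
    }
  }
  new_capped_genome(n, m, perm(cycles, elems = elems))
}

cycle_of <- function(p, x) {
  succ <- match(p$map, p$elems)
  i <- match(as.integer(x), p$elems)
  if (is.na(i)) stop("element not in ground set: ", x)
  pos <- i
  j <- succ[i]
  while (j != i) {
    pos[length(pos) + 1L] <- j
    j <- succ[j]
  }
  p$elems[pos]
}

#' Character class of an element in a capped genome
#'
#' Classifies `x` by its role in the capped genome: `"C5"` (5' cap),
#' `"C3"` (3' cap of a gene-bearing contig), `"N3"` (3' cap of a null
#' contig), `"T"` (first gene after a 5' cap, i.e. a contig tail), or
#' `"O"` (any other gene position).
#'
#' @param x Integer vector of elements of the extended ground set.
#' @param g A `capped_genome`.
#' @return Character vector of class labels.
#' @export
genome_char <- function(x, g) {
  stopifnot(inherits(g, "capped_genome"))
  x <- as.integer(x)
  if (anyNA(match(x, g$elems))) {
    stop("element outside the capped ground set: ",
         paste(x[is.na(match(x, g$elems))], collapse = ", "))
  }
  out <- rep("O", length(x))
  out[x %in% g$fivecaps] <- "C5"
  # tails are the images of the 5' caps, when they are genes
  tails <- perm_apply(g$perm, g$fivecaps)
  out[abs(x) <= g$n & (x %in% tails)] <- "T"
  for (k in which(x %in% g$threecaps)) {
    out[k] <- if (any(abs(cycle_of(g$perm, x[k])) <= g$n)) "C3" else "N3"
  }
  out
}

#' 5' cap of the strand containing an element
#'
#' @param x Integer element of the extended ground set.
#' @param g A `capped_genome`.
#' @return The unique 5'-cap element of the strand cycle containing `x`.
#' @export
five_cap <- function(x, g) {
  stopifnot(inherits(g, "capped_genome"))
  x <- as.integer(x)
  i <- match(x, g$elems)
  if (is.na(i)) stop("element outside the capped ground set: ", x)
  pred <- match(g$elems, g$perm$map)  # predecessor position of each position
  fivepos <- match(g$fivecaps, g$elems)
  j <- i
  for (k in seq_len(length(g$elems) + 1L)) {
    if (j %in% fivepos) return(g$elems[j])
    j <- pred[j]
  }
  stop("strand cycle of ", x, " has no 5' cap")
}

# strand cycles (as element vectors) that carry at least one gene
gene_strands <- function(g) {
  Filter(function(cy) any(abs(cy) <= g$n), perm_cycles(g$perm))
}

#' Read the assembled gene order off a capped genome
#'
#' Requires that the fusion phase is complete, i.e. exactly one contig of
#' the capped genome carries genes.  The canonical strand is the one
#' whose 5' cap is the smallest positive cap present (falling back to
#' smallest absolute value if neither strand has a positive 5' cap); its
#' gene reading, caps stripped, is returned.
#'
#' @param g A `capped_genome`.
#' @return Integer vector of signed gene IDs.
#' @export
uncap_assembly <- function(g) {
  stopifnot(inherits(g, "capped_genome"))
  strands <- gene_strands(g)
  if (length(strands) != 2L) {
    stop("expected exactly one gene-bearing contig (two strands), found ",
         length(strands), " strand(s): fusion phase incomplete?")
  }
  c5 <- vapply(strands, function(cy) cy[cy %in% g$fivecaps][1L], integer(1))
  ord <- positive_first_order(c5)
  strand <- strands[[ord[1L]]]
  c5sel <- c5[ord[1L]]
  k <- match(c5sel, strand)
  if (k > 1L) strand <- c(strand[k:length(strand)], strand[1:(k - 1L)])
  strand[abs(strand) <= g$n]
}

# strand-pairing invariant: pi_hat == Gammahat pi_hat^-1 Gammahat,
# i.e. pi(x) == -pi^-1(-x) for all x
strand_paired <- function(p) {
  all(p$map == -perm_preimage(p, -p$elems))
}

# no cycle contains both i and -i
admissible <- function(p) {
  for (cy in perm_cycles(p)) {
    if (any(cy %in% -cy)) return(FALSE)
  }
  TRUE
}
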