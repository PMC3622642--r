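# GRIMM-dialect text I/O.
#
# A genome file holds one '>'-named record whose body is '$'-terminated
# lines of whitespace-separated signed integers, one line per contig
# (chromosome).  '#' lines are comments.  Only linear contigs ('$') are
# supported; the circular terminator '@' is rejected.

#' Read a genome from a GRIMM-dialect file
#'
#' @param path Path to the file.
#' @param kind `"draft"` (each `$`-terminated line is one contig) or
#'   `"reference"` (exactly one `$` line required).
#' @return A `draft_genome` or `reference_genome`.
#' @examples
#' f <- tempfile()
#' writeLines(c(">draft", "1 4 $", "-5 6 $", "3 2 $"), f)
#' read_genome(f, "draft")
#' @export
read_genome <- function(path, kind = c("draft", "reference")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  name <- NULL
  contigs <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, ">")) {
      if (!is.null(name)) {
        stop(path, ":", ln, ": multiple genome records in one file")
      }
      name <- trimws(substring(line, 2L))
      next
    }
    if (grepl("@", line, fixed = TRUE)) {
      stop(path, ":", ln, ": circular contigs ('@') are unsupported")
    }
    if (!endsWith(line, "$")) {
      stop(path, ":", ln, ": contig line does not end with '$'")
    }
    body <- trimws(substring(line, 1L, nchar(line) - 1L))
    toks <- strsplit(body, "[[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    if (!length(toks)) stop(path, ":", ln, ": empty contig")
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      stop(path, ":", ln, ": malformed token '", toks[which(is.na(vals))[1]], "'")
    }
    contigs[[length(contigs) + 1L]] <- vals
  }
  if (!length(contigs)) stop(path, ": no contig lines found")
  if (kind == "reference") {
    if (length(contigs) != 1L) {
      stop(path, ": a reference genome must have exactly one contig line, found ",
           length(contigs))
    }
    return(reference_genome(contigs[[1]]))
  }
  draft_genome(contigs)
}

#' Write a solved assembly in GRIMM-dialect form
#'
#' Emits the ordered, oriented contig list as comments and the induced
#' signed sequence as a single `$`-terminated line; the file round-trips
#' through [read_genome()].
#'
#' @param x A `block_ordering`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_assembly <- function(x, path) {
  stopifnot(inherits(x, "block_ordering"))
  ostr <- ifelse(x$blocks$orientation > 0, "+", "-")
  lines <- c(
    paste0("# ordering: ", paste0(x$blocks$block, ostr, collapse = " ")),
    paste0("# distance: ", x$distance,
           " (reversals: ", x$n_rev, ", block-interchanges: ", x$n_bi, ")"),
    ">assembly",
    paste(c(x$assembly, "$"), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write the event log of a solved ordering as TSV
#'
#' One row per event with its step number, kind, weight, anchor elements
#' and 2-cycle factors in printed cycle notation.  Cap exchanges and
#' fusions carry weight 0; the weight column sums to the distance.
#'
#' @inheritParams write_assembly
#' @return Invisibly, `path`.
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "block_ordering"))
  df <- events_table(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

events_table <- function(x) {
  if (!length(x$events)) {
    return(data.frame(step = integer(0), kind = character(0), weight = integer(0),
                      anchors = character(0), factors = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    step = seq_along(x$events),
    kind = vapply(x$events, `[[`, character(1), "kind"),
    weight = vapply(x$events, `[[`, integer(1), "weight"),
    anchors = vapply(x$events, function(e) {
      paste(names(e$anchors), e$anchors, sep = "=", collapse = ",")
    }, character(1)),
    factors = vapply(x$events, event_factor_string, character(1)),
    stringsAsFactors = FALSE)
}
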