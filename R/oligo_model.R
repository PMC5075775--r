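#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
WC_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct an annotated oligonucleotide strand
#'
#' An annotated strand is the unit of all sequence design work: an ordered
#' DNA base vector with a set of 1-based positions flagged as locked nucleic
#' acid (LNA) monomers and an explicit 5'/3' polarity of the written string.
#'
#' @param bases character vector of single bases from \code{A,C,G,T}, or a
#'   single string which is split into bases.
#' @param lna_flags integer vector of 1-based positions carrying the LNA
#'   sugar modification; positions are counted along the written strand.
#' @param polarity either \code{"5'->3'"} (default) or \code{"3'->5'"},
#'   giving the direction in which \code{bases} is written.
#' @param name free-text label.
#' @return an object of class \code{annotated_strand}.
#' @export
annotated_strand <- function(bases, lna_flags = integer(0),
                             polarity = "5'->3'", name = "") {
  if (length(bases) == 1L && nchar(bases) > 1L)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(as.character(bases))
  if (length(bases) < 1L)
    stop("strand must contain at least one base")
  bad <- setdiff(unique(bases), DNA_BASES)
  if (length(bad))
    stop("illegal base symbol(s): ", paste(bad, collapse = ", "))
  lna_flags <- sort(unique(as.integer(lna_flags)))
  if (length(lna_flags) && (min(lna_flags) < 1L || max(lna_flags) > length(bases)))
    stop("lna_flags outside [1, ", length(bases), "]")
  if (!polarity %in% c("5'->3'", "3'->5'"))
    stop("polarity must be \"5'->3'\" or \"3'->5'\"")
  structure(list(bases = bases, lna_flags = lna_flags,
                 polarity = polarity, name = name),
            class = "annotated_strand")
}

#' @export
print.annotated_strand <- function(x, ...) {
  cat(sprintf("<annotated_strand> %s (%d nt, %d LNA, %s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$bases), length(x$lna_flags), x$polarity))
  cat(" ", serialize_lna_notation(x), "\n")
  invisible(x)
}

#' @export
length.annotated_strand <- function(x) length(x$bases)

#' @export
`==.annotated_strand` <- function(e1, e2) {
  identical(e1$bases, e2$bases) && identical(e1$lna_flags, e2$lna_flags) &&
    identical(e1$polarity, e2$polarity)
}

#' Parse "+" LNA notation into an annotated strand
#'
#' In the conventional mixmer notation a \code{"+"} marks the immediately
#' following base as an LNA monomer; whitespace is presentation only and is
#' ignored, so \code{"TCC + TCT"} and \code{"TCC+TCT"} parse identically.
#'
#' @param text sequence string containing bases, whitespace and \code{"+"}.
#' @inheritParams annotated_strand
#' @return an \code{annotated_strand}.
#' @examples
#' s <- parse_lna_notation("TCC + TCT CTT TCT + CTT TCT + CTT")
#' s$lna_flags   # 4, 13, 19
#' @export
parse_lna_notation <- function(text, polarity = "5'->3'", name = "") {
  chars <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  if (length(chars) == 0L)
    stop("empty sequence")
  bases <- character(0)
  lna <- integer(0)
  pending_lock <- FALSE
  for (ch in chars) {
    if (ch == "+") {
      if (pending_lock) stop("\"++\" is not valid LNA notation")
      pending_lock <- TRUE
    } else if (ch %in% DNA_BASES || toupper(ch) %in% DNA_BASES) {
      bases <- c(bases, toupper(ch))
      if (pending_lock) {
        lna <- c(lna, length(bases))
        pending_lock <- FALSE
      }
    } else {
      stop("illegal character in sequence: \"", ch, "\"")
    }
  }
  if (pending_lock)
    stop("\"+\" must be followed by a base")
  annotated_strand(bases, lna, polarity = polarity, name = name)
}

#' Serialize an annotated strand to "+" notation
#'
#' Inverse of \code{\link{parse_lna_notation}}: emits the base string with a
#' \code{"+"} before every locked base, optionally grouped into space
#' separated blocks. Round-trips exactly for every valid strand.
#'
#' @param strand an \code{annotated_strand}.
#' @param grouping bases per space-separated block; \code{0} for no grouping.
#' @return a single string.
#' @export
serialize_lna_notation <- function(strand, grouping = 3L) {
  stopifnot(inherits(strand, "annotated_strand"))
  toks <- strand$bases
  toks[strand$lna_flags] <- paste0("+", toks[strand$lna_flags])
  if (grouping > 0L) {
    blocks <- split(toks, ceiling(seq_along(toks) / grouping))
    paste(vapply(blocks, paste, "", collapse = ""), collapse = " ")
  } else {
    paste(toks, collapse = "")
  }
}

#' Watson-Crick complement of a strand
#'
#' Base-wise complement with the polarity label flipped, so the complement of
#' a 5'->3' strand is written 3'->5' in the same left-to-right register.
#' LNA flags are not propagated: the annealing partner is unmodified DNA
#' unless stated otherwise.
#'
#' @param strand an \code{annotated_strand}.
#' @return the complementary \code{annotated_strand}.
#' @export
wc_complement <- function(strand) {
  stopifnot(inherits(strand, "annotated_strand"))
  annotated_strand(unname(WC_PAIR[strand$bases]),
                   integer(0),
                   polarity = if (strand$polarity == "5'->3'") "3'->5'" else "5'->3'",
                   name = if (nzchar(strand$name)) paste0(strand$name, "_complement") else "")
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Base composition of a strand
#'
#' Counts and integer percentages per base (round half up, matching how base
#' content is conventionally tabulated: 13/21 T and 8/21 C print as 62%/38%).
#'
#' @param strand an \code{annotated_strand}.
#' @return list with \code{counts}, \code{percent} (integer, bases present
#'   only), \code{percent_exact}, \code{gc_percent} and \code{length}.
#' @export
base_composition <- function(strand) {
  stopifnot(inherits(strand, "annotated_strand"))
  n <- length(strand$bases)
  counts <- vapply(DNA_BASES, function(b) sum(strand$bases == b), 0L)
  exact <- 100 * counts / n
  structure(list(counts = counts,
                 percent = round_half_up(exact)[counts > 0L],
                 percent_exact = exact,
                 gc_percent = unname(exact["G"] + exact["C"]),
                 length = n),
            class = "composition_report")
}

#' GC content of a strand, in percent (un-rounded)
#' @param strand an \code{annotated_strand}.
#' @return numeric in [0, 100].
#' @export
gc_content <- function(strand) {
  stopifnot(inherits(strand, "annotated_strand"))
  100 * sum(strand$bases %in% c("G", "C")) / length(strand$bases)
}

#' Build a fully annealed duplex
#'
#' Pairs a 5'->3' top strand with a 3'->5' bottom strand position by position
#' and validates Watson-Crick complementarity at every pair. With no bottom
#' strand supplied the exact complement is annealed.
#'
#' @param top \code{annotated_strand}, written 5'->3'.
#' @param bottom \code{annotated_strand} written 3'->5', or \code{NULL}.
#' @return object of class \code{oligo_duplex} with \code{top}, \code{bottom}
#'   and a two-column \code{pairing} matrix.
#' @export
make_duplex <- function(top, bottom = NULL) {
  stopifnot(inherits(top, "annotated_strand"))
  if (top$polarity != "5'->3'") stop("top strand must be written 5'->3'")
  if (is.null(bottom)) bottom <- wc_complement(top)
  if (bottom$polarity != "3'->5'") stop("bottom strand must be written 3'->5'")
  if (length(bottom$bases) != length(top$bases))
    stop("strand lengths differ; only fully paired duplexes are supported")
  ok <- WC_PAIR[top$bases] == bottom$bases
  if (!all(ok))
    stop("mismatched duplex at position(s) ", paste(which(!ok), collapse = ", "))
  pairing <- cbind(top_pos = seq_along(top$bases),
                   bottom_pos = seq_along(top$bases))
  structure(list(top = top, bottom = bottom, pairing = pairing),
            class = "oligo_duplex")
}

#' Write annotated strands as FASTA with "+" LNA markers
#'
#' The sequence line carries the \code{"+"} notation; the header records the
#' name and polarity. Plain FASTA (no \code{"+"}) is read back unchanged.
#'
#' @param strands list of \code{annotated_strand}.
#' @param path output file path.
#' @export
write_lna_fasta <- function(strands, path) {
  if (inherits(strands, "annotated_strand")) strands <- list(strands)
  lines <- unlist(lapply(strands, function(s) {
    c(sprintf(">%s polarity=%s", if (nzchar(s$name)) s$name else "strand",
              s$polarity),
      serialize_lna_notation(s, grouping = 0L))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file in the "+" LNA dialect (or plain FASTA)
#' @param path input file path.
#' @return named list of \code{annotated_strand}.
#' @export
read_lna_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- lapply(seq_along(hdr), function(i) {
    header <- sub("^>", "", lines[hdr[i]])
    name <- strsplit(header, "[[:space:]]+")[[1]][1]
    pol <- if (grepl("polarity=3'->5'", header, fixed = TRUE)) "3'->5'" else "5'->3'"
    seq <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    parse_lna_notation(seq, polarity = pol, name = name)
  })
  names(out) <- vapply(out, function(s) s$name, "")
  out
}
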