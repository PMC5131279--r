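#' Nucleotide sequence objects
#'
#' A `nucleotide_sequence` is an identified, normalized DNA or RNA sequence.
#' The allowed alphabet is `A`, `C`, `G`, `T`, `U`, `N`; any other character
#' (including other IUPAC ambiguity codes) is rejected, because the motif
#' grammar treats every loop position as a concrete nucleotide and `N` as the
#' only wildcard. Lowercase input is accepted and upper-cased with a warning.
#' A sequence is RNA if and only if it contains `U` and no `T`; a sequence
#' containing both `T` and `U` is rejected.
#'
#' @param seq Character scalar, the nucleotide sequence (may be empty).
#' @param id Character scalar identifier (FASTA header token).
#' @param description Optional free-text description (rest of a FASTA header).
#' @return An object of class `nucleotide_sequence`: a list with elements
#'   `id`, `seq` (uppercase), `kind` (`"DNA"` or `"RNA"`) and `description`.
#' @examples
#' nucleotide_sequence("gggagggagggaggg", id = "example")
#' nucleotide_sequence("GGGUAGGGU", id = "rna")$kind
#' @export
nucleotide_sequence <- function(seq, id = "seq", description = "") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq),
            is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[a-z]", seq)) {
    warning("sequence '", id, "': lowercase characters normalized to uppercase",
            call. = FALSE)
    seq <- toupper(seq)
  }
  bad <- regexpr("[^ACGTUN]", seq)
  if (bad != -1L) {
    stop("sequence '", id, "': illegal character '",
         substr(seq, bad, bad), "' at position ", bad, call. = FALSE)
  }
  has_t <- grepl("T", seq, fixed = TRUE)
  has_u <- grepl("U", seq, fixed = TRUE)
  if (has_t && has_u) {
    stop("sequence '", id, "': contains both T and U; cannot classify as DNA or RNA",
         call. = FALSE)
  }
  structure(
    list(id = id, seq = seq, kind = if (has_u) "RNA" else "DNA",
         description = description),
    class = "nucleotide_sequence"
  )
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<nucleotide_sequence> %s (%s, %d nt)\n  %s\n",
              x$id, x$kind, n, shown))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Reads single- or multi-record FASTA (line-wrapped or single-line). The
#' record id is the header text up to the first whitespace; the remainder is
#' kept as the description. Each record is validated and normalized through
#' [nucleotide_sequence()], so DNA/RNA is detected per record and illegal
#' characters are reported with the record id and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of `nucleotide_sequence` objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA in '", path, "': sequence data before first header at line ",
         nonblank[1], call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- nucleotide_sequence(as.character(set[[i]]), id = ids[i],
                                    description = desc[i])
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `nucleotide_sequence` or a list of them.
#' @param path Output path.
#' @param width Line-wrap width for the sequence (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "nucleotide_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "seq"))
  names(set) <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Strand-complement a raw string; U-pairing for RNA, T-pairing for DNA.
complement_string <- function(seq, rna = FALSE) {
  if (rna) chartr("ACGUN", "UGCAN", seq) else chartr("ACGTN", "TGCAN", seq)
}

reverse_string <- function(seq) {
  if (!nchar(seq)) return(seq)
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Reverse complement of a nucleotide sequence
#'
#' Base-pairs and reverses the sequence. DNA pairs A with T, RNA pairs A with
#' U; G pairs with C in both; N maps to N. The sequence kind is preserved.
#' `reverse_complement` is an involution: applying it twice returns the input.
#'
#' @param s A `nucleotide_sequence`, or a plain character scalar (treated as
#'   DNA unless it contains `U`).
#' @return An object of the same type as the input.
#' @examples
#' reverse_complement(nucleotide_sequence("GGGA"))$seq  # "TCCC"
#' reverse_complement("GGGU")                           # "ACCC"
#' @export
reverse_complement <- function(s) UseMethod("reverse_complement")

#' @export
reverse_complement.nucleotide_sequence <- function(s) {
  rc <- reverse_string(complement_string(s$seq, rna = s$kind == "RNA"))
  structure(list(id = s$id, seq = rc, kind = s$kind, description = s$description),
            class = "nucleotide_sequence")
}

#' @export
reverse_complement.character <- function(s) {
  stopifnot(length(s) == 1L)
  reverse_complement(nucleotide_sequence(s))$seq
}

#' Normalize a sequence for scanning
#'
#' Maps U to T so one pattern engine serves both DNA and RNA; the reporting
#' layer restores the original alphabet in hit sequences.
#'
#' @param s A `nucleotide_sequence` or character scalar.
#' @return A character scalar over `{A,C,G,T,N}`.
#' @export
normalize_for_scan <- function(s) {
  seq <- if (inherits(s, "nucleotide_sequence")) s$seq else toupper(s)
  chartr("U", "T", seq)
}

# Restore U in place of T for RNA when reporting hit subsequences.
denormalize_for_report <- function(seq, kind) {
  if (identical(kind, "RNA")) chartr("T", "U", seq) else seq
}
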