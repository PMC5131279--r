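#' Scanner parameters for putative G-quadruplex detection
#'
#' Configures the motif grammar
#' `G{Y1} X{Y2} G{Y1} X{Y2} G{Y1} X{Y2} G{Y1}`: four guanine tracts of
#' `min_tract`..`max_tract` nucleotides separated by three loops of
#' `min_loop`..`max_loop` arbitrary nucleotides (`X` is any of A, C, G, T/U,
#' N). The defaults — tracts 2..7, loops 1..7 — give a maximum motif span of
#' 4*7 + 3*7 = 49 bases. The number of tracts is fixed at four by the grammar.
#'
#' @param min_tract,max_tract Guanine-tract length bounds (defaults 2 and 7).
#' @param min_loop,max_loop Loop length bounds (defaults 1 and 7).
#' @param scan_antisense Scan the reverse-complement strand too (default TRUE).
#' @return An object of class `pqs_params`.
#' @examples
#' max_motif_span(pqs_params())  # 49
#' @export
pqs_params <- function(min_tract = 2L, max_tract = 7L,
                       min_loop = 1L, max_loop = 7L,
                       scan_antisense = TRUE) {
  min_tract <- as.integer(min_tract); max_tract <- as.integer(max_tract)
  min_loop <- as.integer(min_loop); max_loop <- as.integer(max_loop)
  if (is.na(min_tract) || min_tract < 1L || min_tract > max_tract)
    stop("require 1 <= min_tract <= max_tract", call. = FALSE)
  if (is.na(min_loop) || min_loop < 1L || min_loop > max_loop)
    stop("require 1 <= min_loop <= max_loop", call. = FALSE)
  stopifnot(is.logical(scan_antisense), length(scan_antisense) == 1L)
  structure(
    list(min_tract = min_tract, max_tract = max_tract,
         min_loop = min_loop, max_loop = max_loop,
         n_tracts = 4L, scan_antisense = scan_antisense),
    class = "pqs_params"
  )
}

#' @export
print.pqs_params <- function(x, ...) {
  cat(sprintf(
    "<pqs_params> tracts %d..%d, loops %d..%d, 4 tracts, antisense=%s, max span %d nt\n",
    x$min_tract, x$max_tract, x$min_loop, x$max_loop,
    x$scan_antisense, max_motif_span(x)))
  invisible(x)
}

#' Maximum possible motif span
#'
#' The longest subsequence the grammar can accept:
#' `n_tracts * max_tract + (n_tracts - 1) * max_loop`. At the default
#' parameters this is 49 bases; no reported hit can be longer.
#'
#' @param params A [pqs_params()] object.
#' @return Integer span in bases.
#' @export
max_motif_span <- function(params = pqs_params()) {
  stopifnot(inherits(params, "pqs_params"))
  params$n_tracts * params$max_tract + (params$n_tracts - 1L) * params$max_loop
}

pqs_regex <- function(params) {
  g <- sprintf("(G{%d,%d})", params$min_tract, params$max_tract)
  l <- sprintf("([ACGTN]{%d,%d}?)", params$min_loop, params$max_loop)
  paste0(g, l, g, l, g, l, g)
}

empty_hits <- function() {
  df <- data.frame(start = integer(), end = integer(), length = integer(),
                   hit_seq = character(), stringsAsFactors = FALSE)
  df$tract_lengths <- list()
  df$loop_lengths <- list()
  df
}

#' Find putative G-quadruplex motifs on a single strand
#'
#' Scans a normalized sequence left to right for leftmost, non-overlapping
#' matches of the four-tract grammar; after each accepted match, scanning
#' resumes immediately after its end. Within a match, G-tracts are matched
#' greedily (longest first) and loops lazily (shortest first), with full
#' backtracking, so a match is reported whenever any tract/loop assignment
#' exists at that start; the reported decomposition is the one preferred by
#' that order. This tie-break is deterministic and assigns as many guanines
#' as possible to tracts.
#'
#' @param seq Character scalar over `{A,C,G,T,N}` (use [normalize_for_scan()]
#'   for RNA or mixed-case input).
#' @param params A [pqs_params()] object.
#' @return A data.frame with one row per hit: `start`, `end` (1-based,
#'   inclusive), `length`, `hit_seq`, and list-columns `tract_lengths`
#'   (four integers) and `loop_lengths` (three integers).
#' @examples
#' find_pqs_strand("GGGAGGGAGGGAGGG")
#' @export
find_pqs_strand <- function(seq, params = pqs_params()) {
  stopifnot(is.character(seq), length(seq) == 1L, inherits(params, "pqs_params"))
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L)
    stop("unnormalized character '", substr(seq, bad, bad), "' at position ",
         bad, "; scan input must be over {A,C,G,T,N}", call. = FALSE)
  if (!nchar(seq)) return(empty_hits())

  m <- gregexpr(pqs_regex(params), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_hits())

  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  n <- length(starts)
  hits <- data.frame(start = starts, end = starts + lens - 1L, length = lens,
                     hit_seq = substring(seq, starts, starts + lens - 1L),
                     stringsAsFactors = FALSE)
  hits$tract_lengths <- lapply(seq_len(n), function(i) as.integer(cl[i, c(1, 3, 5, 7)]))
  hits$loop_lengths <- lapply(seq_len(n), function(i) as.integer(cl[i, c(2, 4, 6)]))
  hits
}

#' Map reverse-complement coordinates back to input coordinates
#'
#' A hit at 1-based inclusive positions `[start_rc, end_rc]` of the reverse
#' complement of a length-`L` sequence occupies `[L - end_rc + 1,
#' L - start_rc + 1]` of the input. The mapping is an involution.
#'
#' @param start_rc,end_rc 1-based inclusive positions on the reverse
#'   complement; vectors of equal length accepted.
#' @param L Length of the input sequence.
#' @return A list with integer vectors `start` and `end` in input coordinates.
#' @export
map_antisense_coords <- function(start_rc, end_rc, L) {
  start_rc <- as.integer(start_rc); end_rc <- as.integer(end_rc); L <- as.integer(L)
  if (any(start_rc < 1L) || any(end_rc > L) || any(start_rc > end_rc))
    stop("require 1 <= start_rc <= end_rc <= L", call. = FALSE)
  list(start = L - end_rc + 1L, end = L - start_rc + 1L)
}

#' Scan both strands of a sequence for putative G-quadruplex motifs
#'
#' Runs [find_pqs_strand()] on the input (sense) and, unless disabled, on its
#' reverse complement (antisense), with antisense coordinates mapped back to
#' input coordinates. The two scans are independent: non-overlap is enforced
#' per strand, and a sense hit may overlap an antisense hit in input
#' coordinates. Hit sequences are reported 5'->3' on the hit strand, in the
#' input's alphabet (U restored for RNA).
#'
#' @param s A `nucleotide_sequence`, or a character scalar (coerced).
#' @param params A [pqs_params()] object; its `scan_antisense` flag controls
#'   the antisense scan.
#' @return An object of class `g4_scan`: list with `seq_id`, `hits` (a
#'   data.frame with columns `seq_id`, `strand` (`"+"` sense / `"-"`
#'   antisense), `start`, `end`, `length`, `hit_seq`, `tract_lengths`,
#'   `loop_lengths`, sorted by strand then start), counts `n_sense`,
#'   `n_antisense`, `n_total`, the scanned `params`, the input `seq` and its
#'   `length`.
#' @examples
#' scan_pqs("GGGAGGGAGGGAGGG")
#' scan_pqs("CCCTCCCTCCCTCCC")  # one antisense hit
#' @export
scan_pqs <- function(s, params = pqs_params()) {
  if (!inherits(s, "nucleotide_sequence")) s <- nucleotide_sequence(s)
  stopifnot(inherits(params, "pqs_params"))
  norm <- normalize_for_scan(s)
  L <- nchar(norm)

  sense <- find_pqs_strand(norm, params)
  sense$strand <- rep("+", nrow(sense))

  if (params$scan_antisense) {
    rc <- reverse_string(complement_string(norm))
    anti <- find_pqs_strand(rc, params)
    if (nrow(anti)) {
      mapped <- map_antisense_coords(anti$start, anti$end, L)
      anti$start <- mapped$start
      anti$end <- mapped$end
      anti <- anti[order(anti$start), , drop = FALSE]
    }
    anti$strand <- rep("-", nrow(anti))
  } else {
    anti <- sense[0, , drop = FALSE]
  }

  hits <- rbind(sense, anti)
  hits$hit_seq <- denormalize_for_report(hits$hit_seq, s$kind)
  hits <- hits[, c("strand", "start", "end", "length", "hit_seq",
                   "tract_lengths", "loop_lengths")]
  hits <- cbind(seq_id = rep(s$id, nrow(hits)), hits, stringsAsFactors = FALSE)
  rownames(hits) <- NULL

  structure(
    list(seq_id = s$id, kind = s$kind, seq = s$seq, length = L, hits = hits,
         n_sense = nrow(sense), n_antisense = nrow(anti),
         n_total = nrow(hits), params = params),
    class = "g4_scan"
  )
}

#' @export
print.g4_scan <- function(x, ...) {
  cat(sprintf("<g4_scan> %s (%s, %d nt): %d hits (%d sense, %d antisense)\n",
              x$seq_id, x$kind, x$length, x$n_total, x$n_sense, x$n_antisense))
  if (x$n_total) {
    shown <- as.data.frame(x)
    shown$tract_lengths <- vapply(x$hits$tract_lengths, paste, "", collapse = ",")
    shown$loop_lengths <- vapply(x$hits$loop_lengths, paste, "", collapse = ",")
    print(utils::head(shown, 10L), row.names = FALSE)
    if (x$n_total > 10L) cat("... and", x$n_total - 10L, "more hits\n")
  }
  invisible(x)
}

#' @export
summary.g4_scan <- function(object, ...) {
  data.frame(seq_id = object$seq_id, length = object$length,
             n_sense = object$n_sense, n_antisense = object$n_antisense,
             n_total = object$n_total, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.g4_scan <- function(x, ...) x$hits
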