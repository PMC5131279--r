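#' Cumulative guanine content score (cG)
#'
#' Every window of consecutive guanines contributes 10 times its length:
#' each single G scores 10, each GG pair 20, each GGG triplet 30, and so on,
#' counting overlapping windows cumulatively. Equivalently, a maximal run of
#' `L` guanines contributes `10 * L * (L + 1) * (L + 2) / 6`. N contributes
#' nothing and breaks runs. Higher cG relative to cC indicates a region more
#' likely to fold into a G-quadruplex.
#'
#' @param s Character scalar over `{A,C,G,T,U,N}`; U is treated as T.
#' @return Non-negative number; 0 if and only if `s` contains no G.
#' @examples
#' cg_score("G")    # 10
#' cg_score("GG")   # 40
#' cg_score("GGG")  # 100
#' @export
cg_score <- function(s) {
  base_content_score(s, "G")
}

#' Cumulative cytosine content score (cC)
#'
#' Identical to [cg_score()] with cytosine in place of guanine. For any
#' sequence, `cc_score(s)` equals `cg_score` of the (unreversed) complement.
#'
#' @inheritParams cg_score
#' @return Non-negative number; 0 if and only if `s` contains no C.
#' @export
cc_score <- function(s) {
  base_content_score(s, "C")
}

base_content_score <- function(s, base) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  s <- chartr("U", "T", toupper(s))
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L)
    stop("illegal character '", substr(s, bad, bad), "' at position ", bad,
         call. = FALSE)
  if (!nchar(s)) return(0)
  m <- gregexpr(paste0(base, "+"), s)[[1]]
  if (m[1] == -1L) return(0)
  L <- as.numeric(attr(m, "match.length"))
  sum(10 * L * (L + 1) * (L + 2) / 6)
}

#' cG/cC ratio
#'
#' The ratio of the cumulative guanine score to the cumulative cytosine
#' score over the same window. Motifs with a higher cG/cC ratio are more
#' likely to readily fold into a G-quadruplex. When the window contains
#' guanines but no cytosines the ratio is `Inf`; when it contains neither
#' the ratio is undefined and `NA` is returned.
#'
#' @inheritParams cg_score
#' @return A number, `Inf`, or `NA`.
#' @examples
#' cg_cc_ratio("GGGC")  # 10
#' cg_cc_ratio("GGG")   # Inf
#' cg_cc_ratio("ATAT")  # NA
#' @export
cg_cc_ratio <- function(s) {
  cg <- cg_score(s)
  cc <- cc_score(s)
  if (cc > 0) cg / cc else if (cg > 0) Inf else NA_real_
}

#' Score a scanner hit with flanking context
#'
#' Extracts the window `[start - flank, end + flank]` around a hit, clipped
#' to the sequence bounds, and computes cG, cC and their ratio on the hit
#' strand: sense hits are scored on the input text, antisense hits on the
#' reverse complement of the window, since the motif's guanines lie on that
#' strand. `flank = 0` scores the motif alone.
#'
#' @param hit A one-row slice of a `g4_scan` hits data.frame, or any list
#'   with elements `strand` (`"+"`/`"-"`), `start` and `end` in input
#'   coordinates.
#' @param full_seq The scanned `nucleotide_sequence` (or character scalar).
#' @param flank Nucleotides of context requested on each side (default 15).
#' @return An object of class `g4_score`: list with `cG`, `cC`, `ratio`,
#'   `window_start`, `window_end` (actual, clipped, input coordinates) and
#'   `flank` (as requested).
#' @export
score_hit <- function(hit, full_seq, flank = 15L) {
  if (!inherits(full_seq, "nucleotide_sequence"))
    full_seq <- nucleotide_sequence(full_seq)
  flank <- as.integer(flank)
  stopifnot(length(flank) == 1L, !is.na(flank), flank >= 0L)
  start <- as.integer(hit$start); end <- as.integer(hit$end)
  strand <- if (is.null(hit$strand)) "+" else as.character(hit$strand)
  L <- nchar(full_seq$seq)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("hit [", start, ", ", end, "] outside sequence bounds [1, ", L, "]",
         call. = FALSE)
  ws <- max(1L, start - flank)
  we <- min(L, end + flank)
  window <- substr(normalize_for_scan(full_seq), ws, we)
  if (identical(strand, "-"))
    window <- reverse_string(complement_string(window))
  cg <- cg_score(window)
  cc <- cc_score(window)
  structure(
    list(cG = cg, cC = cc,
         ratio = if (cc > 0) cg / cc else if (cg > 0) Inf else NA_real_,
         window_start = ws, window_end = we, flank = flank),
    class = "g4_score"
  )
}

#' @export
print.g4_score <- function(x, ...) {
  cat(sprintf("<g4_score> window [%d, %d] (flank %d): cG=%g cC=%g cG/cC=%s\n",
              x$window_start, x$window_end, x$flank, x$cG, x$cC,
              format(x$ratio)))
  invisible(x)
}

#' Score every hit of a scan
#'
#' Applies [score_hit()] to each hit of a `g4_scan`, appending the columns
#' `cG`, `cC`, `cG_cC_ratio`, `window_start` and `window_end` to the hits
#' table.
#'
#' @param scan A `g4_scan` from [scan_pqs()].
#' @param flank Context on each side of each hit (default 15 nt).
#' @return The `g4_scan` with augmented `hits`.
#' @export
score_scan <- function(scan, flank = 15L) {
  stopifnot(inherits(scan, "g4_scan"))
  full <- structure(list(id = scan$seq_id, seq = scan$seq, kind = scan$kind,
                         description = ""),
                    class = "nucleotide_sequence")
  n <- nrow(scan$hits)
  sc <- lapply(seq_len(n), function(i) score_hit(scan$hits[i, ], full, flank))
  scan$hits$cG <- vapply(sc, `[[`, numeric(1), "cG")
  scan$hits$cC <- vapply(sc, `[[`, numeric(1), "cC")
  scan$hits$cG_cC_ratio <- vapply(sc, `[[`, numeric(1), "ratio")
  scan$hits$window_start <- vapply(sc, `[[`, integer(1), "window_start")
  scan$hits$window_end <- vapply(sc, `[[`, integer(1), "window_end")
  scan
}
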