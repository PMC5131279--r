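# Flat TSV/JSON emission of scanner hits. TSV serializes the tract/loop
# decompositions comma-joined and the cG/cC ratio sentinels as "inf"
# (no cytosine in window) and "NA" (neither base present).

#' Flatten a scan's hits for tabular output
#'
#' Converts the list-columns of a `g4_scan` hits table (or a list of scans,
#' row-bound) into comma-joined strings suitable for TSV.
#'
#' @param x A `g4_scan`, a hits data.frame, or a list of `g4_scan` objects.
#' @return A plain data.frame with only atomic columns.
#' @export
flatten_hits <- function(x) {
  if (inherits(x, "g4_scan")) x <- x$hits
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(s) s$hits))
  x$tract_lengths <- vapply(x$tract_lengths, paste, "", collapse = ",")
  x$loop_lengths <- vapply(x$loop_lengths, paste, "", collapse = ",")
  x
}

format_ratio_tsv <- function(r) {
  ifelse(is.na(r), "NA", ifelse(is.infinite(r), "inf",
                                format(r, digits = 6, trim = TRUE)))
}

write_hits_tsv <- function(hits, path) {
  flat <- flatten_hits(hits)
  if ("cG_cC_ratio" %in% names(flat))
    flat$cG_cC_ratio <- format_ratio_tsv(flat$cG_cC_ratio)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

write_hits_json <- function(scans, path) {
  if (inherits(scans, "g4_scan")) scans <- list(scans)
  hits <- do.call(rbind, lapply(scans, function(s) s$hits))
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    o <- as.list(hits[i, setdiff(names(hits), c("tract_lengths", "loop_lengths"))])
    o$tract_lengths <- hits$tract_lengths[[i]]
    o$loop_lengths <- hits$loop_lengths[[i]]
    if (!is.null(o$cG_cC_ratio)) {
      if (is.na(o$cG_cC_ratio)) o$cG_cC_ratio <- NULL
      else if (is.infinite(o$cG_cC_ratio)) o$cG_cC_ratio <- "inf"
    }
    o
  })
  summaries <- lapply(scans, function(s)
    list(seq_id = s$seq_id, n_sense = s$n_sense, n_antisense = s$n_antisense,
         n_total = s$n_total))
  jsonlite::write_json(list(hits = rows, summary = summaries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
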