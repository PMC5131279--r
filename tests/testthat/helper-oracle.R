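# Independent brute-force oracles. These deliberately share no code with the
# package: the scanner oracle enumerates every (start, t1..t4, l1..l3)
# assignment of the grammar, and the scoring oracle enumerates every
# substring. They are the ground truth the implementation is tested against.

# Exhaustive grammar enumerator with leftmost-nonoverlap selection and the
# same within-match preference (tracts longest first, loops shortest first,
# earlier components varied slowest).
brute_force_pqs <- function(seq, params = pqs_params()) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  grun <- integer(n)
  for (i in rev(seq_len(n)))
    grun[i] <- if (chars[i] == "G") (if (i < n) grun[i + 1L] else 0L) + 1L else 0L
  ts <- rev(seq(params$min_tract, params$max_tract))
  ls <- seq(params$min_loop, params$max_loop)

  find_at <- function(i0) {
    for (t1 in ts) {
      if (grun[i0] < t1) next
      for (l1 in ls) {
        p2 <- i0 + t1 + l1
        if (p2 > n) break
        for (t2 in ts) {
          if (grun[p2] < t2) next
          for (l2 in ls) {
            p3 <- p2 + t2 + l2
            if (p3 > n) break
            for (t3 in ts) {
              if (grun[p3] < t3) next
              for (l3 in ls) {
                p4 <- p3 + t3 + l3
                if (p4 > n) break
                for (t4 in ts) {
                  if (p4 + t4 - 1L > n || grun[p4] < t4) next
                  return(list(tracts = c(t1, t2, t3, t4), loops = c(l1, l2, l3)))
                }
              }
            }
          }
        }
      }
    }
    NULL
  }

  hits <- list()
  pos <- 1L
  while (pos <= n) {
    m <- find_at(pos)
    if (is.null(m)) {
      pos <- pos + 1L
    } else {
      len <- sum(m$tracts) + sum(m$loops)
      hits[[length(hits) + 1L]] <-
        list(start = pos, end = pos + len - 1L,
             tracts = as.integer(m$tracts), loops = as.integer(m$loops))
      pos <- pos + len
    }
  }
  hits
}

oracle_hits_df <- function(hits) {
  data.frame(
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    tracts = vapply(hits, function(h) paste(h$tracts, collapse = ","), ""),
    loops = vapply(hits, function(h) paste(h$loops, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

scanner_hits_df <- function(hits) {
  data.frame(
    start = hits$start, end = hits$end,
    tracts = vapply(hits$tract_lengths, paste, "", collapse = ","),
    loops = vapply(hits$loop_lengths, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
}

# Sum 10 * length over every all-`base` substring (overlapping windows).
brute_content_score <- function(s, base = "G") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  total <- 0
  for (i in seq_len(n)) {
    j <- i
    while (j <= n && chars[j] == base) {
      total <- total + 10 * (j - i + 1)
      j <- j + 1L
    }
  }
  total
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Naive per-record search oracles (no shared code with the store module).
naive_record_text <- function(records, i, fields) {
  vals <- lapply(fields, function(f) {
    v <- records[[f]]
    if (is.list(v)) paste(v[[i]], collapse = "; ") else as.character(v[i])
  })
  tolower(paste(unlist(vals), collapse = "\n"))
}

naive_quick_search_ids <- function(records, query) {
  fields <- c("interaction_id", "category", "protein_name", "protein_synonyms",
              "uniprot_id", "uniprot_entry_name", "organism", "gene_name",
              "gene_synonyms", "protein_fasta", "target_name",
              "target_sequence", "pdb_ids", "interacting_residues",
              "technique", "pmid", "authors")
  keep <- vapply(seq_len(nrow(records)), function(i) {
    grepl(tolower(query), naive_record_text(records, i, fields), fixed = TRUE)
  }, TRUE)
  sort(records$interaction_id[keep])
}

naive_advanced_search_ids <- function(records, criteria) {
  keep <- vapply(seq_len(nrow(records)), function(i) {
    all(vapply(names(criteria), function(f) {
      col <- if (f == "author") "authors" else f
      grepl(tolower(criteria[[f]]), naive_record_text(records, i, col),
            fixed = TRUE)
    }, TRUE))
  }, TRUE)
  sort(records$interaction_id[keep])
}
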