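# Deterministic generators of synthetic scanner inputs with planted ground
# truth and of synthetic interaction records. All randomness is local: the
# caller's RNG state is saved and restored, so generation is a pure function
# of its arguments.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# i.i.d. A/C/G/T background with every GG and CC dinucleotide broken, so at
# the default minimum tract of 2 neither strand can host a guanine tract.
clean_background <- function(n) {
  if (n <= 0L) return(character())
  bg <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3))
  for (i in seq_len(n)[-1]) {
    if (bg[i] %in% c("G", "C") && bg[i] == bg[i - 1L])
      bg[i] <- sample(c("A", "T"), 1L)
  }
  bg
}

sample_motif <- function(params) {
  tracts <- sample(seq(params$min_tract, params$max_tract), 4L, replace = TRUE)
  loops <- sample(seq(params$min_loop, params$max_loop), 3L, replace = TRUE)
  chars <- character()
  for (k in 1:4) {
    chars <- c(chars, rep("G", tracts[k]))
    if (k < 4) chars <- c(chars, sample(c("A", "T"), loops[k], replace = TRUE))
  }
  list(tracts = tracts, loops = loops, chars = chars)
}

#' Generate a sequence with planted G-quadruplex motifs
#'
#' Builds a DNA sequence of the requested length whose background cannot
#' form a motif on either strand, then plants `n_motifs` non-overlapping
#' motifs with tract and loop lengths sampled uniformly over the parameter
#' ranges. Loops are drawn from A/T and the positions flanking each motif
#' are forced to A/T, so every planted motif is recovered by the scanner at
#' its exact coordinates with its exact decomposition. Antisense motifs are
#' planted as their reverse complements (cytosine tracts on the input
#' strand). The assembled sequence is re-scanned and regenerated until the
#' scan reproduces exactly the planted truth (a safeguard; the construction
#' makes accidental motifs impossible at the default minimum tract of 2).
#'
#' @param length Total sequence length in nucleotides.
#' @param n_motifs Number of motifs to plant.
#' @param params A [pqs_params()] object (`min_tract >= 2` required, so the
#'   dinucleotide-free background is guaranteed clean).
#' @param strand_mix Fraction of motifs planted on the antisense strand
#'   (default 0.5); each motif's strand is an independent Bernoulli draw.
#' @param seed Integer seed; the same arguments always produce the same
#'   output, and the caller's RNG state is untouched.
#' @param id Sequence identifier.
#' @return An object of class `planted_truth`: list with `sequence` (a
#'   `nucleotide_sequence`) and `motifs`, a data.frame with columns `start`,
#'   `end`, `strand`, and list-columns `tract_lengths`, `loop_lengths`,
#'   sorted by start.
#' @examples
#' pt <- generate_sequence_with_motifs(500, 3, seed = 42)
#' scan_pqs(pt$sequence)$n_total  # 3
#' @export
generate_sequence_with_motifs <- function(length, n_motifs,
                                          params = pqs_params(),
                                          strand_mix = 0.5, seed = 1L,
                                          id = "synthetic") {
  stopifnot(inherits(params, "pqs_params"), n_motifs >= 0, length >= 0,
            strand_mix >= 0, strand_mix <= 1)
  if (params$min_tract < 2L)
    stop("generator requires min_tract >= 2 for a guaranteed clean background",
         call. = FALSE)
  with_seed(seed, {
    for (attempt in 1:20) {
      motifs <- replicate(n_motifs, sample_motif(params), simplify = FALSE)
      strands <- if (n_motifs)
        ifelse(stats::runif(n_motifs) < strand_mix, "-", "+") else character()
      lens <- vapply(motifs, function(m) length(m$chars), integer(1))
      # stars-and-bars gap layout; >= 2 background nt around every motif
      extra <- length - sum(lens) - 2L * (n_motifs + 1L)
      if (extra < 0L)
        stop("infeasible packing: ", n_motifs, " motifs totalling ", sum(lens),
             " nt (plus buffers) do not fit in ", length, " nt", call. = FALSE)
      gaps <- rep(2L, n_motifs + 1L)
      if (extra > 0L)
        gaps <- gaps + tabulate(sample.int(n_motifs + 1L, extra, replace = TRUE),
                                n_motifs + 1L)
      chars <- clean_background(length)
      pos <- 0L
      starts <- integer(n_motifs); ends <- integer(n_motifs)
      for (k in seq_len(n_motifs)) {
        pos <- pos + gaps[k]
        mchars <- motifs[[k]]$chars
        if (strands[k] == "-")
          mchars <- rev(chartr("ACGT", "TGCA", mchars))
        starts[k] <- pos + 1L
        ends[k] <- pos + length(mchars)
        chars[starts[k]:ends[k]] <- mchars
        # guard the boundaries so greedy tract matching cannot shift
        if (starts[k] > 1L) chars[starts[k] - 1L] <- sample(c("A", "T"), 1L)
        if (ends[k] < length) chars[ends[k] + 1L] <- sample(c("A", "T"), 1L)
        pos <- ends[k]
      }
      truth <- data.frame(start = starts, end = ends, strand = strands,
                          stringsAsFactors = FALSE)
      truth$tract_lengths <- lapply(motifs, function(m) as.integer(m$tracts))
      truth$loop_lengths <- lapply(motifs, function(m) as.integer(m$loops))
      s <- nucleotide_sequence(paste(chars, collapse = ""), id = id)
      if (planted_truth_recovered(s, truth, params)) {
        return(structure(list(sequence = s, motifs = truth),
                         class = "planted_truth"))
      }
    }
    stop("failed to generate a clean planted fixture in 20 attempts",
         call. = FALSE)
  })
}

planted_truth_recovered <- function(s, truth, params) {
  sc <- scan_pqs(s, params)
  hits <- sc$hits
  if (nrow(hits) != nrow(truth)) return(FALSE)
  if (!nrow(truth)) return(TRUE)
  o_h <- order(hits$start, hits$strand)
  o_t <- order(truth$start, truth$strand)
  all(hits$start[o_h] == truth$start[o_t]) &&
    all(hits$end[o_h] == truth$end[o_t]) &&
    all(hits$strand[o_h] == truth$strand[o_t]) &&
    all(mapply(identical, hits$tract_lengths[o_h], truth$tract_lengths[o_t])) &&
    all(mapply(identical, hits$loop_lengths[o_h], truth$loop_lengths[o_t]))
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %s: %d nt, %d planted motifs (%d sense, %d antisense)\n",
              x$sequence$id, nchar(x$sequence$seq), nrow(x$motifs),
              sum(x$motifs$strand == "+"), sum(x$motifs$strand == "-")))
  invisible(x)
}

synthetic_organisms <- c("Homo sapiens", "Mus musculus", "Zea mays",
                         "Saccharomyces cerevisiae", "Escherichia coli",
                         "Drosophila melanogaster")
synthetic_techniques <- c("SPR", "ITC", "EMSA", "CD spectroscopy", "FRET",
                          "NMR", "Fluorescence titration")
synthetic_surnames <- c("Sharma", "Garcia", "Chen", "Okafor", "Nguyen",
                        "Mueller", "Rossi", "Tanaka", "Kowalski", "Silva")

random_target_seq <- function(category) {
  n <- sample(15:30, 1L)
  alpha <- if (category == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  paste(sample(alpha, n, replace = TRUE, prob = c(0.2, 0.15, 0.5, 0.15)),
        collapse = "")
}

# Worked-example records the search tests anchor on. Every field value
# except the protein/gene/id names and the one PMID is synthetic filler.
anchor_records <- function() {
  rbind(
    interaction_record("G4DIP1", "DNA", "Nucleolin",
      protein_synonyms = c("NCL", "C23"),
      uniprot_id = "P19338", uniprot_entry_name = "NUCL_HUMAN",
      organism = "Homo sapiens", gene_name = "NCL",
      target_name = "c-MYC promoter NHE III G-quadruplex",
      target_sequence = "TGGGGAGGGTGGGGAGGGTGGGGAAGG",
      kd = 5e-8, technique = "EMSA", pmid = "19888888",
      authors = c("Sharma", "Chen")),
    interaction_record("G4PIBD28", "DNA", "Nucleoside diphosphate kinase 1",
      protein_synonyms = c("zmNDPK1", "NM23-H2 homologue"),
      uniprot_id = "Q9ZT89", uniprot_entry_name = "NDK1_MAIZE",
      organism = "Zea mays", gene_name = "NDPK1",
      target_name = "G-quadruplex DNA",
      target_sequence = "GGGTTAGGGTTAGGGTTAGGG",
      delta_tm = 8.5, technique = "CD spectroscopy", pmid = "25679041",
      authors = c("Silva", "Kowalski")),
    interaction_record("G4RIP1", "RNA", "FMRP",
      protein_synonyms = c("Fragile X mental retardation protein", "FMR1"),
      uniprot_id = "Q06787", uniprot_entry_name = "FMR1_HUMAN",
      organism = "Homo sapiens", gene_name = "FMR1",
      target_name = "mRNA G-quadruplex",
      target_sequence = "GGGCUGGGCUGGGCUGGG",
      kd = 2e-8, technique = "Fluorescence titration", pmid = "19777777",
      authors = c("Tanaka", "Nguyen"))
  )
}

#' Generate synthetic interaction records
#'
#' Produces `n` valid records with plausible field values: dissociation
#' constants log-uniform over 1e-9..1e-6 M, association constants
#' log-uniform over 1e6..1e9 1/M, melting-temperature shifts uniform over
#' 0..25 deg C (each binding parameter present with probability 0.8),
#' categories split about 50/50, and unique interaction ids. With
#' `anchors = TRUE`, the first three records are fixed worked-example
#' records — a Nucleolin entry under id G4DIP1, an NDPK1/NM23-H2 entry with
#' PMID 25679041, and an FMRP entry — used to anchor search tests.
#'
#' @param n Number of records (anchors counted when requested).
#' @param seed Integer seed; generation is deterministic per seed and leaves
#'   the caller's RNG state untouched.
#' @param anchors Include the three fixed worked-example records first.
#' @return A validated record data.frame with `n` rows.
#' @examples
#' recs <- generate_records(10, seed = 7)
#' nrow(browse_by_category(recs, "DNA")) + nrow(browse_by_category(recs, "RNA"))
#' @export
generate_records <- function(n, seed = 1L, anchors = FALSE) {
  stopifnot(n >= 0)
  base <- if (anchors) anchor_records() else empty_store()
  base <- base[seq_len(min(nrow(base), n)), , drop = FALSE]
  n_rand <- n - nrow(base)
  rows <- with_seed(seed, lapply(seq_len(n_rand), function(i) {
    category <- sample(c("DNA", "RNA"), 1L)
    prefix <- if (category == "DNA") "G4DIP" else "G4RIP"
    nm <- sprintf("Protein %03d", i)
    interaction_record(
      sprintf("%s%03d", prefix, i + 500L), category, nm,
      protein_synonyms = {
        k <- sample(0:2, 1L)
        if (k) sprintf("P%03d-%s", i, c("alpha", "beta")[seq_len(k)]) else character()
      },
      uniprot_id = sprintf("P%05d", sample.int(99999L, 1L)),
      uniprot_entry_name = sprintf("PR%03d_%s", i,
                                   toupper(substr(sample(synthetic_organisms, 1L), 1, 5))),
      organism = sample(synthetic_organisms, 1L),
      gene_name = sprintf("GENE%03d", i),
      gene_synonyms = if (stats::runif(1) < 0.5) sprintf("gn%03d", i) else character(),
      target_name = sprintf("%s target %03d G-quadruplex", category, i),
      target_sequence = random_target_seq(category),
      delta_tm = if (stats::runif(1) < 0.8) stats::runif(1, 0, 25) else NA_real_,
      ka = if (stats::runif(1) < 0.8) 10^stats::runif(1, 6, 9) else NA_real_,
      kd = if (stats::runif(1) < 0.8) 10^stats::runif(1, -9, -6) else NA_real_,
      pdb_ids = if (stats::runif(1) < 0.3) sprintf("%d%s", sample(1:9, 1L),
                    paste(sample(LETTERS, 3L, TRUE), collapse = "")) else character(),
      interacting_residues = if (stats::runif(1) < 0.5) {
        k <- sample(1:3, 1L)
        sprintf("%s%d", sample(c("R", "K", "F", "Y", "W"), k, TRUE),
                sample(10:300, k))
      } else character(),
      technique = sample(synthetic_techniques, 1L),
      pmid = sprintf("%08d", sample.int(99999999L, 1L)),
      authors = sample(synthetic_surnames, sample(1:3, 1L)))
  }))
  out <- do.call(rbind, c(list(base), rows))
  rownames(out) <- NULL
  validate_store(out, context = "generate_records")
}
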