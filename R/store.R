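# Flat-file store of curated G-quadruplex-protein interaction records.
# A store is a plain data.frame with one row per interaction: scalar text
# columns, ";"-separable list-columns, and optional numeric binding
# parameters (delta_tm in degrees C, ka in 1/M, kd in M).

record_fields <- c(
  "interaction_id", "category", "protein_name", "protein_synonyms",
  "uniprot_id", "uniprot_entry_name", "organism", "gene_name",
  "gene_synonyms", "protein_fasta", "target_name", "target_sequence",
  "delta_tm", "ka", "kd", "pdb_ids", "interacting_residues",
  "technique", "pmid", "authors"
)
record_list_fields <- c("protein_synonyms", "gene_synonyms", "pdb_ids",
                        "interacting_residues", "authors")
record_numeric_fields <- c("delta_tm", "ka", "kd")

# The ten advanced-search criteria; "author" queries the authors list.
search_fields <- c("interaction_id", "target_name", "target_sequence",
                   "protein_name", "uniprot_id", "uniprot_entry_name",
                   "gene_name", "gene_synonyms", "pmid", "author")

empty_store <- function() {
  df <- as.data.frame(
    setNames(rep(list(character()), length(record_fields)), record_fields),
    stringsAsFactors = FALSE)
  for (f in record_list_fields) df[[f]] <- list()
  for (f in record_numeric_fields) df[[f]] <- numeric()
  df
}

#' Construct one interaction record
#'
#' Builds a one-row record data.frame describing a curated interaction
#' between a protein and a G-quadruplex-forming nucleic acid. Unsupplied
#' text fields default to empty, list fields to empty lists, and binding
#' parameters (`delta_tm` in deg C, `ka` in 1/M, `kd` in M) to `NA`.
#'
#' @param interaction_id Unique store key, e.g. `"G4DIP1"` (free-form).
#' @param category `"DNA"` or `"RNA"`: which kind of G-quadruplex the
#'   protein interacts with.
#' @param protein_name Interacting protein name.
#' @param ... Further fields by name: `protein_synonyms`, `uniprot_id`,
#'   `uniprot_entry_name`, `organism`, `gene_name`, `gene_synonyms`,
#'   `protein_fasta`, `target_name`, `target_sequence`, `delta_tm`, `ka`,
#'   `kd`, `pdb_ids`, `interacting_residues`, `technique`, `pmid`,
#'   `authors`. List fields accept character vectors.
#' @return A one-row data.frame with the full record schema.
#' @examples
#' r <- interaction_record("G4DIP1", "DNA", "Nucleolin",
#'                         uniprot_id = "P19338", pmid = "12345678")
#' validate_record(r)
#' @export
interaction_record <- function(interaction_id, category, protein_name, ...) {
  extra <- list(...)
  unknown <- setdiff(names(extra), record_fields)
  if (length(unknown))
    stop("unknown record field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- list(interaction_id = interaction_id, category = category,
               protein_name = protein_name)
  vals <- c(vals, extra)
  row <- list()
  for (f in setdiff(record_fields, record_list_fields)) {
    v <- vals[[f]]
    row[[f]] <- if (f %in% record_numeric_fields) {
      if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
    } else {
      if (is.null(v) || !length(v)) "" else as.character(v)
    }
  }
  df <- as.data.frame(row, stringsAsFactors = FALSE)
  for (f in record_list_fields) {
    v <- vals[[f]]
    df[[f]] <- list(if (is.null(v)) character() else as.character(v))
  }
  df[, record_fields]
}

#' Validate one interaction record
#'
#' Checks the record invariants: non-empty `interaction_id`; `category` in
#' DNA/RNA; `target_sequence` (when present) over the nucleotide alphabet
#' consistent with the category (T only in DNA, U only in RNA); `kd` and
#' `ka` strictly positive when present; `pmid` all digits when present.
#'
#' @param r A one-row record data.frame (or list with the same fields).
#' @return Character vector of violations; empty when the record is valid.
#' @export
validate_record <- function(r) {
  v <- character()
  id <- as.character(r$interaction_id)
  if (!length(id) || is.na(id) || !nzchar(id))
    v <- c(v, "interaction_id: empty")
  cat <- as.character(r$category)
  if (!length(cat) || is.na(cat) || !cat %in% c("DNA", "RNA")) {
    v <- c(v, "category: must be DNA or RNA")
  } else {
    ts <- toupper(as.character(r$target_sequence))
    if (length(ts) && !is.na(ts) && nzchar(ts)) {
      alpha <- if (cat == "DNA") "[^ACGTN]" else "[^ACGUN]"
      if (grepl(alpha, ts))
        v <- c(v, "target_sequence: alphabet/category mismatch")
    }
  }
  for (f in c("ka", "kd")) {
    x <- suppressWarnings(as.numeric(r[[f]]))
    if (length(x) && !is.na(x) && x <= 0)
      v <- c(v, paste0(f, ": must be positive when present"))
  }
  pm <- as.character(r$pmid)
  if (length(pm) && !is.na(pm) && nzchar(pm) && grepl("[^0-9]", pm))
    v <- c(v, "pmid: non-digit characters")
  v
}

validate_store <- function(records, context = "store") {
  ids <- records$interaction_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(context, ": duplicate interaction_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(records))) {
    v <- validate_record(records[i, ])
    if (length(v))
      stop(context, ": record '", ids[i], "' invalid: ",
           paste(v, collapse = "; "), call. = FALSE)
  }
  invisible(records)
}

#' Load interaction records from TSV or JSON
#'
#' TSV files must have a header row with the full schema; list-valued fields
#' are split on `";"`. JSON files hold an array of objects with snake_case
#' keys; list fields are arrays and absent numerics null. All records are
#' validated on load; duplicated interaction ids or invariant violations are
#' errors.
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return A record data.frame (one row per interaction).
#' @seealso [save_records()], [validate_record()]
#' @export
load_records <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                             na.strings = character())
    missing <- setdiff(record_fields, names(raw))
    if (length(missing))
      stop("TSV '", path, "' missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    df <- raw[, record_fields, drop = FALSE]
    for (f in record_list_fields) {
      df[[f]] <- lapply(strsplit(df[[f]], ";", fixed = TRUE),
                        function(x) trimws(x[nzchar(trimws(x))]))
    }
    for (f in record_numeric_fields) {
      x <- df[[f]]
      num <- suppressWarnings(as.numeric(x))
      bad <- nzchar(x) & is.na(num)
      if (any(bad))
        stop("non-numeric ", f, " in record '",
             df$interaction_id[which(bad)[1]], "'", call. = FALSE)
      df[[f]] <- ifelse(nzchar(x), num, NA_real_)
    }
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(objs, function(o) {
      do.call(interaction_record, c(
        list(interaction_id = o$interaction_id %||% "",
             category = o$category %||% "",
             protein_name = o$protein_name %||% ""),
        o[intersect(names(o), setdiff(record_fields,
            c("interaction_id", "category", "protein_name")))] |>
          lapply(function(x) if (is.list(x)) unlist(x) else x)))
    })
    df <- if (length(rows)) do.call(rbind, rows) else empty_store()
  }
  rownames(df) <- NULL
  validate_store(df, context = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save interaction records to TSV or JSON
#'
#' Inverse of [load_records()]: a load/save/load round trip preserves record
#' content exactly.
#'
#' @param records A record data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
save_records <- function(records, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    flat <- records
    for (f in record_list_fields)
      flat[[f]] <- vapply(records[[f]], paste, "", collapse = ";")
    for (f in record_numeric_fields) {
      x <- records[[f]]
      flat[[f]] <- ifelse(is.na(x), "", sprintf("%.17g", x))
    }
    utils::write.table(flat[, record_fields], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    objs <- lapply(seq_len(nrow(records)), function(i) {
      o <- list()
      for (f in record_fields) {
        val <- if (f %in% record_list_fields) records[[f]][[i]]
               else records[[f]][i]
        o[[f]] <- if (f %in% record_numeric_fields && is.na(val)) NULL else val
      }
      o
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Browse records by nucleic-acid category
#'
#' The store's two browsing shelves: proteins interacting with G-quadruplex
#' DNA, and with G-quadruplex RNA.
#'
#' @param records A record data.frame.
#' @param category `"DNA"` or `"RNA"`.
#' @return Matching records sorted by `interaction_id`.
#' @export
browse_by_category <- function(records, category = c("DNA", "RNA")) {
  category <- match.arg(category)
  out <- records[records$category == category, , drop = FALSE]
  out <- out[order(out$interaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One lower-cased haystack string per record covering all searchable text.
record_haystacks <- function(records, fields = NULL) {
  if (is.null(fields))
    fields <- setdiff(record_fields, record_numeric_fields)
  parts <- lapply(fields, function(f) {
    if (f %in% record_list_fields)
      vapply(records[[f]], paste, "", collapse = "; ")
    else
      as.character(records[[f]])
  })
  tolower(do.call(paste, c(parts, sep = "\n")))
}

#' Quick search across all record text
#'
#' Case-insensitive substring match of a single query string against every
#' searchable text field (protein name and synonyms, target name and
#' sequences, UniProt id and entry name, gene name and synonyms, authors,
#' technique, PMID and interaction id). Querying `"FMRP"` returns the
#' records with FMRP as interacting protein; querying an interaction id
#' returns exactly that record.
#'
#' @param records A record data.frame.
#' @param query Non-empty query string.
#' @return Matching records sorted by `interaction_id`.
#' @export
quick_search <- function(records, query) {
  stopifnot(is.character(query), length(query) == 1L)
  if (is.na(query) || !nzchar(query))
    stop("empty query; use browse_by_category() to list records", call. = FALSE)
  hit <- grepl(tolower(query), record_haystacks(records), fixed = TRUE)
  out <- records[hit, , drop = FALSE]
  out <- out[order(out$interaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Advanced search on specific fields
#'
#' Conjunctive (AND) search over up to ten criteria: `interaction_id`,
#' `target_name`, `target_sequence`, `protein_name`, `uniprot_id`,
#' `uniprot_entry_name`, `gene_name`, `gene_synonyms`, `pmid` and `author`.
#' Each criterion is a case-insensitive substring match on its field; a
#' record must satisfy every supplied criterion.
#'
#' @param records A record data.frame.
#' @param criteria Named character vector or named list mapping field names
#'   to query strings; at least one criterion.
#' @return Matching records sorted by `interaction_id`.
#' @export
advanced_search <- function(records, criteria) {
  criteria <- unlist(criteria)
  if (!length(criteria) || is.null(names(criteria)) || any(!nzchar(names(criteria))))
    stop("criteria must be a named vector with at least one entry", call. = FALSE)
  unknown <- setdiff(names(criteria), search_fields)
  if (length(unknown))
    stop("unknown search field(s): ", paste(unknown, collapse = ", "),
         "; valid fields: ", paste(search_fields, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  for (f in names(criteria)) {
    col <- if (f == "author") "authors" else f
    hay <- record_haystacks(records, fields = col)
    keep <- keep & grepl(tolower(criteria[[f]]), hay, fixed = TRUE)
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$interaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
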