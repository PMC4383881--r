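#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

# The twenty proteinogenic residues; "X" is additionally tolerated in sequences.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

TERMINUS_CATEGORIES <- c("canonical", "alt_splicing", "alt_translation",
                         "cleavage", "experimental", "isoform_inferred")

KB_TABLES <- c("proteins", "features", "termini", "cleavages",
               "inhibitions", "orthologs")

kb_template <- function(table) {
  switch(table,
    proteins = data.frame(accession = character(), name = character(),
                          species = character(), is_canonical = logical(),
                          parent_accession = character(),
                          sequence = character(), stringsAsFactors = FALSE),
    features = data.frame(protein_accession = character(), kind = character(),
                          start = integer(), end = integer(),
                          description = character(), stringsAsFactors = FALSE),
    termini = data.frame(protein_accession = character(),
                         terminus_type = character(), position = integer(),
                         category = character(), source_id = character(),
                         confidence = numeric(), stringsAsFactors = FALSE),
    cleavages = data.frame(protease_accession = character(),
                           substrate_accession = character(),
                           p1_position = integer(), evidence_source = character(),
                           species = character(), stringsAsFactors = FALSE),
    inhibitions = data.frame(inhibitor_accession = character(),
                             protease_accession = character(),
                             evidence_source = character(),
                             stringsAsFactors = FALSE),
    orthologs = data.frame(accession_a = character(), species_a = character(),
                           accession_b = character(), species_b = character(),
                           score = numeric(), stringsAsFactors = FALSE),
    stop("unknown knowledgebase table: ", table)
  )
}

coerce_table <- function(df, table) {
  tmpl <- kb_template(table)
  for (col in names(tmpl)) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
    mode_fun <- switch(class(tmpl[[col]])[1],
                       character = as.character, integer = as.integer,
                       numeric = as.numeric, logical = as.logical)
    df[[col]] <- mode_fun(df[[col]])
  }
  df <- df[, names(tmpl), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct an in-memory terminus knowledgebase
#'
#' Bundles the six entity tables of the flat-file knowledgebase dialect into a
#' single validated object: proteins (with their amino-acid sequences),
#' position-specific features, terminus evidences, protease cleavage events
#' (identified by the P1 residue of the scissile bond), inhibitor--protease
#' inhibition events, and cross-species ortholog pairs.
#'
#' Duplicate cleavage tuples (protease, substrate, P1) are collapsed.
#'
#' @param proteins data frame with columns accession, name, species,
#'   is_canonical, parent_accession, sequence
#' @param features data frame with columns protein_accession, kind, start,
#'   end, description
#' @param termini data frame with columns protein_accession, terminus_type
#'   ("N"/"C"), position, category, source_id, confidence
#' @param cleavages data frame with columns protease_accession,
#'   substrate_accession, p1_position, evidence_source, species
#' @param inhibitions data frame with columns inhibitor_accession,
#'   protease_accession, evidence_source
#' @param orthologs data frame with columns accession_a, species_a,
#'   accession_b, species_b, score
#' @return an object of class \code{termikit_kb}
#' @export
kb <- function(proteins = NULL, features = NULL, termini = NULL,
               cleavages = NULL, inhibitions = NULL, orthologs = NULL) {
  tabs <- list(proteins = proteins, features = features, termini = termini,
               cleavages = cleavages, inhibitions = inhibitions,
               orthologs = orthologs)
  out <- lapply(KB_TABLES, function(tb) {
    df <- tabs[[tb]]
    if (is.null(df)) kb_template(tb) else coerce_table(as.data.frame(df), tb)
  })
  names(out) <- KB_TABLES
  out$cleavages <- collapse_cleavages(out$cleavages)
  structure(out, class = "termikit_kb")
}

collapse_cleavages <- function(cl) {
  if (nrow(cl) == 0) return(cl)
  key <- paste(cl$protease_accession, cl$substrate_accession, cl$p1_position,
               sep = "\r")
  cl <- cl[!duplicated(key), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

kb_sequence <- function(kb, accession) {
  i <- match(accession, kb$proteins$accession)
  kb$proteins$sequence[i]
}

#' @export
print.termikit_kb <- function(x, ...) {
  cat("<termikit knowledgebase>\n")
  for (tb in KB_TABLES) cat(sprintf("  %-12s %6d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' @export
#' @method summary termikit_kb
summary.termikit_kb <- function(object, ...) {
  v <- validate_kb(object)
  print(object)
  cat(sprintf("  canonical proteins: %d, isoforms: %d\n",
              sum(object$proteins$is_canonical),
              sum(!object$proteins$is_canonical)))
  cat(sprintf("  validation violations: %d\n", nrow(v)))
  invisible(object)
}

violation <- function(entity, id, field, rule, message) {
  data.frame(entity = entity, id = id, field = field, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(entity = character(), id = character(), field = character(),
             rule = character(), message = character(), stringsAsFactors = FALSE)
}

#' Validate a knowledgebase against its referential-integrity rules
#'
#' Checks accession uniqueness, sequence alphabet, isoform parent links,
#' feature and terminus position bounds, cleavage P1 bounds
#' (1 <= P1 <= length - 1), resolution of every cross-reference,
#' self-inhibition, and ortholog species constraints. Violations are returned
#' as data, not raised.
#'
#' @param kb a \code{termikit_kb}
#' @param orthologs_one_to_one if TRUE, additionally require at most one
#'   ortholog pair per (accession, partner species)
#' @return data frame of violations (entity, id, field, rule, message);
#'   zero rows for a well-formed knowledgebase
#' @export
validate_kb <- function(kb, orthologs_one_to_one = FALSE) {
  stopifnot(inherits(kb, "termikit_kb"))
  v <- list(no_violations())
  pr <- kb$proteins
  acc <- pr$accession
  seqlen <- setNames(nchar(pr$sequence), acc)

  dup <- unique(acc[duplicated(acc)])
  for (a in dup)
    v[[length(v) + 1]] <- violation("protein", a, "accession",
      "accessions unique", sprintf("accession '%s' occurs more than once", a))
  bad_seq <- which(is.na(pr$sequence) | nchar(pr$sequence) < 1)
  for (i in bad_seq)
    v[[length(v) + 1]] <- violation("protein", acc[i], "sequence",
      "sequence length >= 1", "empty or missing sequence")
  bad_alpha <- which(grepl(sprintf("[^%sX]", paste(AA20, collapse = "")),
                           pr$sequence))
  for (i in bad_alpha)
    v[[length(v) + 1]] <- violation("protein", acc[i], "sequence",
      "20-letter alphabet plus X", "sequence contains invalid residue letters")
  iso <- which(!pr$is_canonical)
  for (i in iso) {
    p <- pr$parent_accession[i]
    j <- match(p, acc)
    if (is.na(p) || is.na(j))
      v[[length(v) + 1]] <- violation("protein", acc[i], "parent_accession",
        "isoform names existing canonical parent",
        sprintf("parent '%s' not found", if (is.na(p)) "" else p))
    else if (!pr$is_canonical[j])
      v[[length(v) + 1]] <- violation("protein", acc[i], "parent_accession",
        "isoform names existing canonical parent",
        sprintf("parent '%s' is not canonical", p))
  }

  ft <- kb$features
  for (i in seq_len(nrow(ft))) {
    a <- ft$protein_accession[i]
    if (!a %in% acc) {
      v[[length(v) + 1]] <- violation("feature", sprintf("row %d", i),
        "protein_accession", "accession resolves",
        sprintf("protein '%s' not found", a))
      next
    }
    if (is.na(ft$start[i]) || is.na(ft$end[i]) || ft$start[i] < 1 ||
        ft$start[i] > ft$end[i] || ft$end[i] > seqlen[[a]])
      v[[length(v) + 1]] <- violation("feature", sprintf("row %d", i),
        "start/end", "1 <= start <= end <= length(sequence)",
        sprintf("feature %s..%s on '%s' (length %d)",
                ft$start[i], ft$end[i], a, seqlen[[a]]))
  }

  tm <- kb$termini
  for (i in seq_len(nrow(tm))) {
    a <- tm$protein_accession[i]
    if (!a %in% acc) {
      v[[length(v) + 1]] <- violation("terminus", sprintf("row %d", i),
        "protein_accession", "accession resolves",
        sprintf("protein '%s' not found", a))
      next
    }
    if (is.na(tm$position[i]) || tm$position[i] < 1 ||
        tm$position[i] > seqlen[[a]])
      v[[length(v) + 1]] <- violation("terminus", sprintf("row %d", i),
        "position", "1 <= position <= length(sequence)",
        sprintf("position %s on '%s' (length %d)", tm$position[i], a,
                seqlen[[a]]))
    if (!tm$terminus_type[i] %in% c("N", "C"))
      v[[length(v) + 1]] <- violation("terminus", sprintf("row %d", i),
        "terminus_type", "terminus_type in {N, C}",
        sprintf("invalid type '%s'", tm$terminus_type[i]))
    if (!tm$category[i] %in% TERMINUS_CATEGORIES)
      v[[length(v) + 1]] <- violation("terminus", sprintf("row %d", i),
        "category", "category in enum",
        sprintf("invalid category '%s'", tm$category[i]))
    if (identical(tm$category[i], "isoform_inferred") &&
        (is.na(tm$source_id[i]) || !nzchar(tm$source_id[i])))
      v[[length(v) + 1]] <- violation("terminus", sprintf("row %d", i),
        "source_id", "isoform_inferred references source evidence",
        "isoform_inferred evidence lacks a source_id")
  }

  cl <- kb$cleavages
  for (i in seq_len(nrow(cl))) {
    pa <- cl$protease_accession[i]
    sa <- cl$substrate_accession[i]
    if (!pa %in% acc)
      v[[length(v) + 1]] <- violation("cleavage", sprintf("row %d", i),
        "protease_accession", "accession resolves",
        sprintf("protease '%s' not found", pa))
    if (!sa %in% acc) {
      v[[length(v) + 1]] <- violation("cleavage", sprintf("row %d", i),
        "substrate_accession", "accession resolves",
        sprintf("substrate '%s' not found", sa))
      next
    }
    if (is.na(cl$p1_position[i]) || cl$p1_position[i] < 1 ||
        cl$p1_position[i] > seqlen[[sa]] - 1)
      v[[length(v) + 1]] <- violation("cleavage", sprintf("row %d", i),
        "p1_position", "1 <= p1 <= length(substrate) - 1",
        sprintf("P1 %s on '%s' (length %d)", cl$p1_position[i], sa,
                seqlen[[sa]]))
  }

  ih <- kb$inhibitions
  for (i in seq_len(nrow(ih))) {
    ia <- ih$inhibitor_accession[i]
    pa <- ih$protease_accession[i]
    if (!ia %in% acc)
      v[[length(v) + 1]] <- violation("inhibition", sprintf("row %d", i),
        "inhibitor_accession", "accession resolves",
        sprintf("inhibitor '%s' not found", ia))
    if (!pa %in% acc)
      v[[length(v) + 1]] <- violation("inhibition", sprintf("row %d", i),
        "protease_accession", "accession resolves",
        sprintf("protease '%s' not found", pa))
    if (!is.na(ia) && !is.na(pa) && ia == pa)
      v[[length(v) + 1]] <- violation("inhibition", sprintf("row %d", i),
        "inhibitor_accession", "self-inhibition rejected",
        sprintf("'%s' inhibits itself", ia))
  }

  ot <- kb$orthologs
  bad_sp <- which(ot$species_a == ot$species_b)
  for (i in bad_sp)
    v[[length(v) + 1]] <- violation("ortholog", sprintf("row %d", i),
      "species", "species_a != species_b",
      sprintf("pair %s/%s shares species '%s'", ot$accession_a[i],
              ot$accession_b[i], ot$species_a[i]))
  if (orthologs_one_to_one && nrow(ot) > 0) {
    key <- paste(ot$accession_a, ot$species_b, sep = "\r")
    for (i in which(duplicated(key)))
      v[[length(v) + 1]] <- violation("ortholog", sprintf("row %d", i),
        "accession_a/species_b", "one pair per (accession, partner species)",
        sprintf("duplicate ortholog for '%s' in '%s'", ot$accession_a[i],
                ot$species_b[i]))
  }

  do.call(rbind, v)
}

stop_on_violations <- function(v, context) {
  if (nrow(v) == 0) return(invisible(NULL))
  shown <- head(v, 10)
  msg <- paste(sprintf("  [%s %s] %s: %s (%s)", shown$entity, shown$id,
                       shown$field, shown$message, shown$rule),
               collapse = "\n")
  stop(sprintf("%s: %d validation violation(s)\n%s%s", context, nrow(v), msg,
               if (nrow(v) > 10) "\n  ..." else ""), call. = FALSE)
}

read_kb_table <- function(path, table) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", na.strings = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  tmpl <- kb_template(table)
  # protein sequences travel in sequences.fasta, not in the TSV
  missing_cols <- setdiff(setdiff(names(tmpl), "sequence"), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("table %s: missing column(s) %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  # integer columns carry positions; reject non-integer content with the line
  for (col in names(tmpl)[vapply(tmpl, is.integer, logical(1))]) {
    raw <- df[[col]]
    parsed <- suppressWarnings(as.integer(raw))
    numval <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & (is.na(parsed) | parsed != numval))
    if (length(bad) > 0)
      stop(sprintf("table %s, line %d: malformed %s value '%s' (not an integer)",
                   basename(path), bad[1] + 1L, col, raw[bad[1]]),
           call. = FALSE)
    df[[col]] <- parsed
  }
  if (!is.null(df$is_canonical))
    df$is_canonical <- toupper(df$is_canonical) %in% c("TRUE", "T", "1", "YES")
  coerce_table(df, table)
}

#' Load a knowledgebase from a flat-file directory
#'
#' Reads the knowledgebase dialect: six UTF-8 tab-separated tables
#' (\code{proteins.tsv}, \code{features.tsv}, \code{termini.tsv},
#' \code{cleavages.tsv}, \code{inhibitions.tsv}, \code{orthologs.tsv}; one
#' header row each) plus \code{sequences.fasta} holding the protein sequences
#' keyed by accession. Duplicate cleavage tuples are collapsed; the result is
#' validated and loading fails with a descriptive error on any violation.
#'
#' @param directory_path directory holding the dialect files
#' @param min_confidence optional filter: terminus evidences with a confidence
#'   below this value are dropped at load (evidences without a confidence are
#'   kept)
#' @param strict when TRUE (default) loading fails on any validation
#'   violation; when FALSE the knowledgebase is returned regardless, so the
#'   violations can be inspected with \code{\link{validate_kb}}
#' @return a validated \code{termikit_kb}
#' @export
load_kb <- function(directory_path, min_confidence = NULL, strict = TRUE) {
  files <- c(paste0(KB_TABLES, ".tsv"), "sequences.fasta")
  for (f in files)
    if (!file.exists(file.path(directory_path, f)))
      stop(sprintf("missing table: %s (in %s)", f, directory_path),
           call. = FALSE)
  tabs <- lapply(KB_TABLES, function(tb)
    read_kb_table(file.path(directory_path, paste0(tb, ".tsv")), tb))
  names(tabs) <- KB_TABLES

  fasta_path <- file.path(directory_path, "sequences.fasta")
  fasta <- if (file.size(fasta_path) == 0) Biostrings::AAStringSet() else
    Biostrings::readAAStringSet(fasta_path)
  seqs <- setNames(as.character(fasta), sub("\\s.*$", "", names(fasta)))
  tabs$proteins$sequence <- unname(seqs[tabs$proteins$accession])
  orphan <- setdiff(names(seqs), tabs$proteins$accession)
  if (length(orphan) > 0)
    stop(sprintf("sequences.fasta: %d record(s) without a proteins.tsv row (e.g. '%s')",
                 length(orphan), orphan[1]), call. = FALSE)
  missing_seq <- tabs$proteins$accession[is.na(tabs$proteins$sequence)]
  if (length(missing_seq) > 0)
    stop(sprintf("sequences.fasta: no sequence for accession '%s'",
                 missing_seq[1]), call. = FALSE)

  if (!is.null(min_confidence)) {
    keep <- is.na(tabs$termini$confidence) |
      tabs$termini$confidence >= min_confidence
    tabs$termini <- tabs$termini[keep, , drop = FALSE]
  }

  out <- kb(proteins = tabs$proteins, features = tabs$features,
            termini = tabs$termini, cleavages = tabs$cleavages,
            inhibitions = tabs$inhibitions, orthologs = tabs$orthologs)
  if (strict)
    stop_on_violations(validate_kb(out),
                       sprintf("load_kb('%s')", directory_path))
  out
}

#' Write a knowledgebase to a flat-file directory
#'
#' Emits the dialect files read by \code{\link{load_kb}}. Loading the written
#' directory returns the same knowledgebase up to row order.
#'
#' @param kb a validated \code{termikit_kb}
#' @param directory_path output directory (created if absent)
#' @export
write_kb <- function(kb, directory_path) {
  stopifnot(inherits(kb, "termikit_kb"))
  stop_on_violations(validate_kb(kb), "write_kb")
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  for (tb in KB_TABLES) {
    df <- kb[[tb]]
    if (tb == "proteins") df$sequence <- NULL
    write.table(df, file.path(directory_path, paste0(tb, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  seqs <- Biostrings::AAStringSet(setNames(kb$proteins$sequence,
                                           kb$proteins$accession))
  Biostrings::writeXStringSet(seqs, file.path(directory_path,
                                              "sequences.fasta"), width = 70L)
  invisible(directory_path)
}
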