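# Sequence-context mapping of termini and cleavage sites between related
# sequences (isoforms, transcript products, alternative translation starts).
# All mapping is exact 20-residue (or truncated) substring matching: a window
# maps only when it occurs exactly once in the target sequence.

#' Build the local sequence-context window of a terminus or cleavage site
#'
#' The context of an N-terminus is the 20 residues starting at it, of a
#' C-terminus the 20 residues ending at it, and of a cleavage the 10 residues
#' on either side of the scissile bond (P10..P1 | P1'..P10'). Windows are
#' truncated at the protein ends.
#'
#' @param sequence protein sequence (character scalar)
#' @param position 1-based residue index: the terminal residue for termini,
#'   the P1 residue for cleavages
#' @param anchor one of "follows_N_terminus", "precedes_C_terminus",
#'   "surrounds_cleavage"
#' @return list with \code{residues} (the window string), \code{anchor}, and
#'   \code{left_len} (residues left of the bond; cleavage windows only)
#' @export
context_window <- function(sequence, position,
                           anchor = c("follows_N_terminus",
                                      "precedes_C_terminus",
                                      "surrounds_cleavage")) {
  anchor <- match.arg(anchor)
  len <- nchar(sequence)
  stopifnot(position >= 1, position <= len)
  if (anchor == "follows_N_terminus") {
    res <- substr(sequence, position, min(len, position + 19L))
    left_len <- NA_integer_
  } else if (anchor == "precedes_C_terminus") {
    res <- substr(sequence, max(1L, position - 19L), position)
    left_len <- NA_integer_
  } else {
    stopifnot(position <= len - 1L)
    left <- substr(sequence, max(1L, position - 9L), position)
    right <- substr(sequence, position + 1L, min(len, position + 10L))
    res <- paste0(left, right)
    left_len <- nchar(left)
  }
  list(residues = res, anchor = anchor, left_len = left_len)
}

#' Find all exact occurrences of a context window in a target sequence
#'
#' Exact string matching, no mismatches or gaps; overlapping occurrences are
#' all reported.
#'
#' @param window a window from \code{\link{context_window}}, or a plain
#'   character scalar
#' @param target_sequence sequence to search
#' @return integer vector of 1-based start positions, ascending (empty if the
#'   window does not occur)
#' @export
match_context <- function(window, target_sequence) {
  pat <- if (is.list(window)) window$residues else window
  stopifnot(is.character(pat), nzchar(pat))
  if (nchar(pat) > nchar(target_sequence)) return(integer(0))
  hits <- Biostrings::matchPattern(pat, Biostrings::AAString(target_sequence))
  sort(Biostrings::start(hits))
}

map_window_status <- function(window, target_sequence, min_window = 1L) {
  pat <- if (is.list(window)) window$residues else window
  if (nchar(pat) < min_window)
    return(list(status = "window_too_short", position = NA_integer_))
  m <- match_context(pat, target_sequence)
  if (length(m) == 0) list(status = "unmapped", position = NA_integer_)
  else if (length(m) > 1) list(status = "ambiguous", position = NA_integer_)
  else list(status = "mapped", position = m)
}

empty_mapping_report <- function() {
  data.frame(entry_kind = character(), source_accession = character(),
             target_accession = character(), terminus_type = character(),
             source_position = integer(), status = character(),
             position = integer(), source_id = character(),
             stringsAsFactors = FALSE)
}

#' Map the termini of a transcript-derived protein product onto a canonical
#' sequence
#'
#' The first 20 residues of the transcript product are located in the
#' canonical sequence to place an alternative-splicing N-terminus evidence;
#' the last 20 residues place the corresponding C-terminus evidence. Windows
#' shorter than 20 (short products) are used at their full truncated length.
#' A window matching zero times or more than once yields no evidence, only a
#' diagnostic.
#'
#' @param transcript_protein_sequence the translated transcript product
#' @param canonical_sequence the reference protein sequence
#' @param canonical_accession accession recorded on emitted evidences
#' @return list with \code{evidences} (terminus-evidence data frame rows) and
#'   \code{diagnostics} (data frame: terminus_type, status)
#' @export
map_transcript_termini <- function(transcript_protein_sequence,
                                   canonical_sequence,
                                   canonical_accession = NA_character_) {
  stopifnot(nzchar(transcript_protein_sequence), nzchar(canonical_sequence))
  tlen <- nchar(transcript_protein_sequence)
  ev <- list(kb_template("termini"))
  diag <- list()
  n_win <- substr(transcript_protein_sequence, 1L, min(20L, tlen))
  r <- map_window_status(n_win, canonical_sequence)
  if (r$status == "mapped") {
    ev[[length(ev) + 1]] <- data.frame(
      protein_accession = canonical_accession, terminus_type = "N",
      position = r$position, category = "alt_splicing",
      source_id = "transcript", confidence = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    diag[[length(diag) + 1]] <- data.frame(
      terminus_type = "N",
      status = if (r$status == "ambiguous") "ambiguous mapping" else "unmapped",
      stringsAsFactors = FALSE)
  }
  c_win <- substr(transcript_protein_sequence, max(1L, tlen - 19L), tlen)
  r <- map_window_status(c_win, canonical_sequence)
  if (r$status == "mapped") {
    ev[[length(ev) + 1]] <- data.frame(
      protein_accession = canonical_accession, terminus_type = "C",
      position = r$position + nchar(c_win) - 1L, category = "alt_splicing",
      source_id = "transcript", confidence = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    diag[[length(diag) + 1]] <- data.frame(
      terminus_type = "C",
      status = if (r$status == "ambiguous") "ambiguous mapping" else "unmapped",
      stringsAsFactors = FALSE)
  }
  list(evidences = do.call(rbind, ev),
       diagnostics = if (length(diag)) do.call(rbind, diag) else
         data.frame(terminus_type = character(), status = character(),
                    stringsAsFactors = FALSE))
}

#' Map a translation-initiation-site window onto a canonical sequence
#'
#' Places the first (at most) 20 residues translated from a reported
#' alternative initiation site on the canonical protein sequence, emitting an
#' alternative-translation N-terminus evidence on a unique exact match.
#'
#' @param translated_window amino-acid string of at most 20 residues starting
#'   at the reported initiation site
#' @param canonical_sequence the reference protein sequence
#' @param canonical_accession accession recorded on the emitted evidence
#' @return list with \code{evidence} (one-row terminus data frame, or zero
#'   rows) and \code{diagnostic} (NA or "ambiguous mapping"/"unmapped")
#' @export
map_tis_n_terminus <- function(translated_window, canonical_sequence,
                               canonical_accession = NA_character_) {
  stopifnot(nzchar(translated_window), nchar(translated_window) <= 20L)
  r <- map_window_status(translated_window, canonical_sequence)
  if (r$status == "mapped") {
    list(evidence = data.frame(
           protein_accession = canonical_accession, terminus_type = "N",
           position = r$position, category = "alt_translation",
           source_id = "tis", confidence = NA_real_, stringsAsFactors = FALSE),
         diagnostic = NA_character_)
  } else {
    list(evidence = kb_template("termini"),
         diagnostic = if (r$status == "ambiguous") "ambiguous mapping" else
           "unmapped")
  }
}

#' Translate a coding nucleotide sequence with the standard genetic code
#'
#' Convenience for preparing translation-initiation windows; translation stops
#' at the first stop codon, which is not included.
#'
#' @param coding_sequence DNA string (length a multiple of 3 is not required;
#'   trailing partial codons are ignored)
#' @return amino-acid string
#' @export
translate_cds <- function(coding_sequence) {
  n <- nchar(coding_sequence) %/% 3L * 3L
  if (n == 0L) return("")
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(coding_sequence, 1L, n)))))
  sub("\\*.*$", "", aa)
}

#' Propagate terminus evidences and cleavage sites across isoforms
#'
#' For every terminus evidence and cleavage site in the knowledgebase, the
#' 20-residue sequence context is extracted from the source protein and
#' located in every other isoform of the same family (canonical and isoforms,
#' in both directions). On a unique exact match a mapped entry is added:
#' termini with category \code{isoform_inferred} and a \code{source_id}
#' referencing the original evidence; cleavages with an
#' \code{isoform_inferred:} evidence source. Ambiguous and unmatched contexts
#' (e.g. spanning an isoform indel) are skipped and counted in the mapping
#' report. Previously inferred entries are never re-propagated, so the
#' operation is idempotent.
#'
#' @param kb a validated \code{termikit_kb}
#' @param min_window minimum context length (residues) required to attempt a
#'   mapping; shorter windows are reported as \code{window_too_short}
#' @return the augmented knowledgebase, with the mapping report available via
#'   \code{\link{mapping_report}}
#' @export
propagate_across_isoforms <- function(kb, min_window = 8L) {
  stopifnot(inherits(kb, "termikit_kb"))
  pr <- kb$proteins
  family_of <- ifelse(pr$is_canonical, pr$accession, pr$parent_accession)
  seqs <- stats::setNames(pr$sequence, pr$accession)
  fam_members <- split(pr$accession, family_of)

  report <- list(empty_mapping_report())
  new_termini <- list()
  new_cleavages <- list()

  existing_term_key <- with(kb$termini, paste(protein_accession, terminus_type,
                                              position, category, source_id,
                                              sep = "\r"))
  existing_clv_key <- with(kb$cleavages, paste(protease_accession,
                                               substrate_accession,
                                               p1_position, sep = "\r"))

  tm <- kb$termini[kb$termini$category != "isoform_inferred", , drop = FALSE]
  for (i in seq_len(nrow(tm))) {
    a <- tm$protein_accession[i]
    sibs <- setdiff(fam_members[[family_of[match(a, pr$accession)]]], a)
    if (length(sibs) == 0) next
    anchor <- if (tm$terminus_type[i] == "N") "follows_N_terminus" else
      "precedes_C_terminus"
    win <- context_window(seqs[[a]], tm$position[i], anchor)
    src_id <- paste(a, tm$terminus_type[i], tm$position[i], tm$category[i],
                    sep = ":")
    for (b in sibs) {
      r <- map_window_status(win, seqs[[b]], min_window)
      pos <- if (r$status == "mapped") {
        if (anchor == "follows_N_terminus") r$position else
          r$position + nchar(win$residues) - 1L
      } else NA_integer_
      report[[length(report) + 1]] <- data.frame(
        entry_kind = "terminus", source_accession = a, target_accession = b,
        terminus_type = tm$terminus_type[i], source_position = tm$position[i],
        status = r$status, position = pos, source_id = src_id,
        stringsAsFactors = FALSE)
      if (r$status != "mapped") next
      key <- paste(b, tm$terminus_type[i], pos, "isoform_inferred", src_id,
                   sep = "\r")
      if (key %in% existing_term_key) next
      existing_term_key <- c(existing_term_key, key)
      new_termini[[length(new_termini) + 1]] <- data.frame(
        protein_accession = b, terminus_type = tm$terminus_type[i],
        position = pos, category = "isoform_inferred", source_id = src_id,
        confidence = tm$confidence[i], stringsAsFactors = FALSE)
    }
  }

  cl <- kb$cleavages[!startsWith(kb$cleavages$evidence_source,
                                 "isoform_inferred:"), , drop = FALSE]
  for (i in seq_len(nrow(cl))) {
    a <- cl$substrate_accession[i]
    sibs <- setdiff(fam_members[[family_of[match(a, pr$accession)]]], a)
    if (length(sibs) == 0) next
    win <- context_window(seqs[[a]], cl$p1_position[i], "surrounds_cleavage")
    src_id <- paste(cl$protease_accession[i], a, cl$p1_position[i], sep = ":")
    for (b in sibs) {
      r <- map_window_status(win, seqs[[b]], min_window)
      pos <- if (r$status == "mapped") r$position + win$left_len - 1L else
        NA_integer_
      report[[length(report) + 1]] <- data.frame(
        entry_kind = "cleavage", source_accession = a, target_accession = b,
        terminus_type = NA_character_, source_position = cl$p1_position[i],
        status = r$status, position = pos, source_id = src_id,
        stringsAsFactors = FALSE)
      if (r$status != "mapped") next
      key <- paste(cl$protease_accession[i], b, pos, sep = "\r")
      if (key %in% existing_clv_key) next
      existing_clv_key <- c(existing_clv_key, key)
      new_cleavages[[length(new_cleavages) + 1]] <- data.frame(
        protease_accession = cl$protease_accession[i],
        substrate_accession = b, p1_position = pos,
        evidence_source = paste0("isoform_inferred:", src_id),
        species = cl$species[i], stringsAsFactors = FALSE)
    }
  }

  out <- kb
  if (length(new_termini) > 0)
    out$termini <- rbind(out$termini, do.call(rbind, new_termini))
  if (length(new_cleavages) > 0)
    out$cleavages <- collapse_cleavages(rbind(out$cleavages,
                                              do.call(rbind, new_cleavages)))
  rownames(out$termini) <- NULL
  attr(out, "mapping_report") <- do.call(rbind, report)
  out
}

#' Retrieve the mapping report attached by isoform propagation
#'
#' @param kb a knowledgebase returned by \code{\link{propagate_across_isoforms}}
#' @return data frame with one row per attempted (entry, target isoform)
#'   mapping and its status (mapped, ambiguous, unmapped, window_too_short)
#' @export
mapping_report <- function(kb) {
  rep <- attr(kb, "mapping_report")
  if (is.null(rep)) empty_mapping_report() else rep
}
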