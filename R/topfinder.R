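# The terminus-annotation engine: locate each submitted terminal peptide on
# its protein, classify the terminus by origin, annotate position-specific
# features, and compute summary and per-protease enrichment statistics.
#
# Position conventions: all positions are 1-based residue indices. A cleavage
# is identified by its P1 residue; the neo-N-terminus it creates sits at
# P1+1 and the neo-C-terminus at P1.

QUERY_CATEGORIES <- c("canonical", "alt_splicing", "alt_translation",
                      "cleaved", "experimental")

#' Locate a terminal peptide on a protein sequence
#'
#' Exact substring search of the peptide in the protein sequence. A unique
#' hit locates the terminus: for an N-terminal peptide the terminus is the
#' first residue of the hit, for a C-terminal peptide the last. Zero hits
#' give status \code{not_found}; two or more give \code{ambiguous} with all
#' hit positions recorded.
#'
#' @param query list or one-row data frame with accession, peptide,
#'   terminus_type ("N"/"C"), and optionally quantity and label
#' @param protein one-row slice of a knowledgebase proteins table, or NULL
#'   for an unknown accession
#' @return a \code{terminus_annotation} (status and position filled)
#' @export
locate_terminus <- function(query, protein = NULL) {
  q <- as.list(query)
  stopifnot(!is.null(q$accession), !is.null(q$peptide),
            q$terminus_type %in% c("N", "C"))
  if (nchar(q$peptide) < 4)
    stop("peptide length must be >= 4")
  ann <- structure(list(query = q, status = "unknown_protein",
                        position = NA_integer_, all_positions = integer(0),
                        categories = character(0),
                        matched_evidence = kb_template("termini"),
                        protease_matches = cbind(kb_template("cleavages"),
                                                 offset = integer(0)),
                        features_n_terminal = kb_template("features"),
                        features_c_terminal = kb_template("features"),
                        features_at_position = kb_template("features")),
                   class = "terminus_annotation")
  if (is.null(protein) || nrow(as.data.frame(protein)) == 0) return(ann)
  protein <- as.data.frame(protein)
  hits <- match_context(q$peptide, protein$sequence[1])
  pos <- if (q$terminus_type == "N") hits else hits + nchar(q$peptide) - 1L
  if (length(hits) == 0) {
    ann$status <- "not_found"
  } else if (length(hits) > 1) {
    ann$status <- "ambiguous"
    ann$all_positions <- pos
  } else {
    ann$status <- "located"
    ann$position <- pos
    ann$all_positions <- pos
  }
  ann
}

#' Classify a located terminus by its origin
#'
#' Assigns origin categories by matching knowledgebase evidence on the same
#' protein and terminus type within +/-\code{window} residues of the located
#' position (accounting for exopeptidase ragging): terminus evidences map to
#' canonical / alt_splicing / alt_translation / experimental (evidence of
#' category \code{cleavage} maps to \code{cleaved}); cleavage events match by
#' the P1 convention (an N-terminus at position t matches a cleavage with
#' P1 = t-1; a C-terminus at t matches P1 = t) and assign \code{cleaved}
#' together with the responsible proteases. Isoform-inferred evidences
#' contribute the category of their source evidence.
#'
#' @param annotation a located \code{terminus_annotation}
#' @param kb a validated \code{termikit_kb}
#' @param window maximum residue offset (0..10) tolerated when matching
#' @return the annotation with categories, matched evidences and protease
#'   matches filled
#' @export
classify_terminus <- function(annotation, kb, window = 0L) {
  stopifnot(inherits(annotation, "terminus_annotation"),
            window >= 0, window <= 10)
  if (annotation$status != "located") return(annotation)
  acc <- annotation$query$accession
  type <- annotation$query$terminus_type
  pos <- annotation$position

  ev <- kb$termini[kb$termini$protein_accession == acc &
                     kb$termini$terminus_type == type &
                     abs(kb$termini$position - pos) <= window, , drop = FALSE]
  cats <- character(0)
  if (nrow(ev) > 0) {
    evcat <- ev$category
    # isoform-inferred evidence carries its source evidence's category in the
    # source_id ("accession:type:position:category")
    inf <- evcat == "isoform_inferred"
    evcat[inf] <- vapply(strsplit(ev$source_id[inf], ":", fixed = TRUE),
                         function(x) x[length(x)], character(1))
    map <- c(canonical = "canonical", alt_splicing = "alt_splicing",
             alt_translation = "alt_translation", cleavage = "cleaved",
             experimental = "experimental")
    cats <- unname(map[evcat[evcat %in% names(map)]])
  }
  clv <- kb$cleavages[kb$cleavages$substrate_accession == acc, , drop = FALSE]
  implied_p1 <- if (type == "N") pos - 1L else pos
  hit <- abs(clv$p1_position - implied_p1) <= window
  clv <- clv[hit, , drop = FALSE]
  if (nrow(clv) > 0) {
    cats <- c(cats, "cleaved")
    clv$offset <- clv$p1_position - implied_p1
    annotation$protease_matches <- clv
  }
  annotation$categories <- intersect(QUERY_CATEGORIES, unique(cats))
  annotation$matched_evidence <- ev
  annotation
}

#' Partition protein features around a located terminus
#'
#' Each feature of the protein is placed N-terminal to the terminus
#' (\code{end < position}), C-terminal to it (\code{start > position}), or at
#' the position (\code{start <= position <= end}). For an N-terminal query
#' the N-terminal features are lost from the fragment and the C-terminal ones
#' retained; for a C-terminal query the roles reverse.
#'
#' @param annotation a located \code{terminus_annotation}
#' @param kb a validated \code{termikit_kb}
#' @return the annotation with the three feature lists filled
#' @export
annotate_features <- function(annotation, kb) {
  stopifnot(inherits(annotation, "terminus_annotation"))
  if (annotation$status != "located") return(annotation)
  ft <- kb$features[kb$features$protein_accession ==
                      annotation$query$accession, , drop = FALSE]
  pos <- annotation$position
  annotation$features_n_terminal <- ft[ft$end < pos, , drop = FALSE]
  annotation$features_c_terminal <- ft[ft$start > pos, , drop = FALSE]
  annotation$features_at_position <-
    ft[ft$start <= pos & ft$end >= pos, , drop = FALSE]
  annotation
}

#' One-sided Fisher exact enrichment probability
#'
#' Enrichment tail of the Fisher exact test on the 2x2 table
#' \code{[[k, n-k], [K, M-K]]}: the hypergeometric upper tail P(X >= k) with
#' population n+M, k+K successes and n draws. This is the test behind the
#' per-protease enrichment table, where k of the n cleavage-derived list
#' termini are attributed to the protease, against a background of K of the M
#' distinct database cleavage sites on the list's proteins.
#'
#' @param k list termini attributed to the protease
#' @param n total cleavage-derived list termini
#' @param K database cleavage sites of the protease on the list's proteins
#' @param M total database cleavage sites on the list's proteins
#' @return the one-sided p-value
#' @export
fisher_enrichment_p <- function(k, n, K, M) {
  if (any(is.na(c(k, n, K, M))) || k < 0 || k > n || K < 0 || K > M ||
      n < 1 || M < 1)
    stop("fisher_enrichment_p: require 0 <= k <= n, 0 <= K <= M, n >= 1, M >= 1")
  stats::phyper(k - 1, k + K, n + M - k - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard BH step-up over the supplied p-values, returned in input order.
#'
#' @param p_values numeric vector of p-values in [0,1]
#' @return q-values in input order
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("bh_adjust: p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-protease enrichment statistics from count columns
#'
#' Computes fold enrichment \code{(k/n)/(K/M)}, fold coverage \code{k/K} and
#' the one-sided Fisher p-value for one protease's counts. BH adjustment over
#' a set of proteases is applied by \code{\link{protease_enrichment_table}}
#' (or \code{\link{bh_adjust}} directly).
#'
#' @inheritParams fisher_enrichment_p
#' @return one-row data frame: k, n, K, M, fold_enrichment, fold_coverage,
#'   p_value
#' @export
enrichment_stats <- function(k, n, K, M) {
  data.frame(k = k, n = n, K = K, M = M,
             fold_enrichment = (k / n) / (K / M),
             fold_coverage = k / K,
             p_value = fisher_enrichment_p(k, n, K, M))
}

#' Protease enrichment table over a classified query list
#'
#' Identified proteases are those matching at least one list terminus. The
#' test counts are: n = number of list termini classified as cleaved (each
#' terminus once, even when matched by several proteases); k = cleaved list
#' termini matched by the protease; M = distinct database cleavage sites
#' (substrate, P1) on the list's proteins attributed to any identified
#' protease (a site shared by two proteases counts once in M but contributes
#' to both proteases' K); K = those sites attributed to the protease. The
#' q-value is the BH adjustment over all identified proteases.
#'
#' @param annotations list of classified \code{terminus_annotation}s
#' @param kb a validated \code{termikit_kb}
#' @return data frame with one row per identified protease (columns
#'   protease_accession, protease_name, k, n, K, M, fold_enrichment,
#'   fold_coverage, p_value, q_value), ordered by ascending p then accession;
#'   zero rows (with a "diagnostic" attribute) when no list terminus is
#'   cleavage-derived
#' @export
protease_enrichment_table <- function(annotations, kb) {
  empty <- data.frame(protease_accession = character(),
                      protease_name = character(), k = integer(),
                      n = integer(), K = integer(), M = integer(),
                      fold_enrichment = numeric(), fold_coverage = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  cleaved <- Filter(function(a) a$status == "located" &&
                      "cleaved" %in% a$categories, annotations)
  n <- length(cleaved)
  if (n == 0) {
    attr(empty, "diagnostic") <- "no cleavage-derived termini in the list"
    return(empty)
  }
  prot_per_term <- lapply(cleaved, function(a)
    unique(a$protease_matches$protease_accession))
  identified <- sort(unique(unlist(prot_per_term)))
  if (length(identified) == 0) {
    attr(empty, "diagnostic") <- "no terminus could be attributed to a protease"
    return(empty)
  }
  k <- vapply(identified, function(p)
    sum(vapply(prot_per_term, function(x) p %in% x, logical(1))), integer(1))

  list_proteins <- unique(vapply(annotations, function(a)
    a$query$accession, character(1)))
  list_proteins <- intersect(list_proteins, kb$proteins$accession)
  sites <- kb$cleavages[kb$cleavages$substrate_accession %in% list_proteins &
                          kb$cleavages$protease_accession %in% identified, ,
                        drop = FALSE]
  site_key <- paste(sites$substrate_accession, sites$p1_position, sep = "\r")
  M <- length(unique(site_key))
  K <- vapply(identified, function(p)
    length(unique(site_key[sites$protease_accession == p])), integer(1))

  p_val <- vapply(seq_along(identified), function(i)
    fisher_enrichment_p(k[i], n, K[i], M), numeric(1))
  out <- data.frame(
    protease_accession = identified,
    protease_name = kb$proteins$name[match(identified,
                                           kb$proteins$accession)],
    k = unname(k), n = n, K = unname(K), M = M,
    fold_enrichment = (k / n) / (K / M), fold_coverage = k / K,
    p_value = p_val, q_value = bh_adjust(p_val), stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$protease_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Counts of located termini per exact origin-category subset
#'
#' Tallies the located termini by the exact subset of the five origin
#' categories each carries (the counts behind the category-overlap Venn
#' diagram). Subsets with zero count are omitted; termini with no category
#' are counted under the empty subset "".
#'
#' @param annotations list of classified \code{terminus_annotation}s
#' @return data frame with columns subset (categories joined by "+") and
#'   count; the counts sum to the number of located termini
#' @export
venn_counts <- function(annotations) {
  located <- Filter(function(a) a$status == "located", annotations)
  keys <- vapply(located, function(a)
    paste(intersect(QUERY_CATEGORIES, a$categories), collapse = "+"),
    character(1))
  if (length(keys) == 0)
    return(data.frame(subset = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(keys)
  out <- data.frame(subset = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$subset), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Binary substrate-by-protease matrix of cleavage attributions
#'
#' One row per located terminus with at least one protease match (labeled
#' accession:position), one column per matching protease; a cell is 1 when
#' the protease is attributed the terminus. Rows and columns are ordered by
#' descending marginal totals, ties broken by accession then position — a
#' deterministic stand-in for the clustered display.
#'
#' @param annotations list of classified \code{terminus_annotation}s
#' @return integer matrix with dimnames (possibly 0 x 0)
#' @export
substrate_protease_matrix <- function(annotations) {
  hits <- Filter(function(a) a$status == "located" &&
                   nrow(a$protease_matches) > 0, annotations)
  if (length(hits) == 0) return(matrix(integer(0), 0, 0))
  labels <- vapply(hits, function(a)
    paste0(a$query$accession, ":", a$position), character(1))
  prots <- sort(unique(unlist(lapply(hits, function(a)
    a$protease_matches$protease_accession))))
  rows <- sort(unique(labels))
  m <- matrix(0L, length(rows), length(prots),
              dimnames = list(rows, prots))
  for (i in seq_along(hits))
    m[labels[i], unique(hits[[i]]$protease_matches$protease_accession)] <- 1L
  ord_split <- function(lbl) {
    acc <- sub(":[0-9]+$", "", lbl)
    pos <- as.integer(sub("^.*:", "", lbl))
    list(acc = acc, pos = pos)
  }
  rs <- ord_split(rownames(m))
  m <- m[order(-rowSums(m), rs$acc, rs$pos), , drop = FALSE]
  m <- m[, order(-colSums(m), colnames(m)), drop = FALSE]
  m
}

kb_residue_frequencies <- function(kb) {
  if (nrow(kb$proteins) == 0)
    return(stats::setNames(rep(1 / 20, 20), AA20))
  counts <- table(factor(unlist(strsplit(kb$proteins$sequence, "")),
                         levels = AA20))
  freqs <- as.numeric(counts) / sum(counts)
  stats::setNames(freqs, AA20)
}

#' Position-specific residue frequencies around termini with significance
#'
#' Builds a frequency-based sequence-logo matrix over the residues at offsets
#' -span..+span around each located terminus (offset 0 is the terminal
#' residue), excluding termini that carry only translational categories
#' (canonical / alternative translation), since those reflect genome-encoded
#' starts rather than processing. Per offset and residue, the observed
#' fraction is compared with a background frequency by a two-sided exact
#' binomial test; cells with p below \code{alpha} are flagged significant.
#'
#' @param annotations list of classified \code{terminus_annotation}s
#' @param kb a validated \code{termikit_kb}
#' @param span residues per side of the terminus
#' @param alpha probability cutoff for flagging a cell
#' @param background optional named residue-frequency vector; defaults to the
#'   residue frequencies over all knowledgebase sequences
#' @return object of class \code{logo_matrix}: offsets, counts, frequencies,
#'   background, p_values, significant, direction (+1 enriched / -1
#'   depleted), n_per_offset
#' @export
ice_logo <- function(annotations, kb, span = 8L, alpha = 0.05,
                     background = NULL) {
  stopifnot(span >= 1, alpha > 0, alpha <= 1)
  if (is.null(background)) background <- kb_residue_frequencies(kb)
  stopifnot(all(AA20 %in% names(background)))
  background <- background[AA20] / sum(background[AA20])

  eligible <- Filter(function(a) {
    if (a$status != "located") return(FALSE)
    cats <- a$categories
    !(length(cats) > 0 && all(cats %in% c("canonical", "alt_translation")))
  }, annotations)
  offsets <- seq(-span, span)
  counts <- matrix(0L, length(offsets), 20,
                   dimnames = list(as.character(offsets), AA20))
  for (a in eligible) {
    seqs <- kb_sequence(kb, a$query$accession)
    at <- a$position + offsets
    ok <- at >= 1 & at <= nchar(seqs)
    res <- substring(seqs, at[ok], at[ok])
    for (j in seq_along(res))
      if (res[j] %in% AA20)
        counts[which(ok)[j], res[j]] <- counts[which(ok)[j], res[j]] + 1L
  }
  n_off <- rowSums(counts)
  freq <- counts / ifelse(n_off == 0, 1, n_off)
  pmat <- matrix(NA_real_, length(offsets), 20,
                 dimnames = dimnames(counts))
  for (i in seq_along(offsets)) {
    if (n_off[i] == 0) next
    for (r in AA20) {
      bg <- background[[r]]
      x <- counts[i, r]
      pmat[i, r] <- if (bg <= 0) {
        if (x > 0) 0 else 1
      } else if (bg >= 1) {
        if (x < n_off[i]) 0 else 1
      } else stats::binom.test(x, n_off[i], bg)$p.value
    }
  }
  sig <- !is.na(pmat) & pmat < alpha
  structure(list(offsets = offsets, residues = AA20, counts = counts,
                 frequencies = freq, background = background,
                 p_values = pmat, significant = sig,
                 direction = sign(sweep(freq, 2, background)),
                 n_per_offset = n_off, alpha = alpha,
                 n_sequences = length(eligible),
                 diagnostic = if (length(eligible) == 0)
                   "no eligible sequences" else NA_character_),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo matrix> %d sequences, offsets %+d..%+d, alpha %g\n",
              x$n_sequences, min(x$offsets), max(x$offsets), x$alpha))
  cat(sprintf("  significant cells: %d of %d tested\n",
              sum(x$significant, na.rm = TRUE), sum(!is.na(x$p_values))))
  invisible(x)
}

logo_to_table <- function(logo) {
  grid <- expand.grid(offset = logo$offsets, residue = logo$residues,
                      stringsAsFactors = FALSE)
  i <- cbind(match(as.character(grid$offset), rownames(logo$counts)),
             match(grid$residue, colnames(logo$counts)))
  data.frame(offset = grid$offset, residue = grid$residue,
             count = logo$counts[i], frequency = logo$frequencies[i],
             background = logo$background[grid$residue],
             p_value = logo$p_values[i], significant = logo$significant[i],
             stringsAsFactors = FALSE)
}

annotation_to_row <- function(a) {
  fmt_feat <- function(ft) paste(sprintf("%s:%d-%d", ft$kind, ft$start,
                                         ft$end), collapse = ";")
  data.frame(
    accession = a$query$accession, peptide = a$query$peptide,
    terminus_type = a$query$terminus_type,
    quantity = if (is.null(a$query$quantity)) NA_real_ else
      as.numeric(a$query$quantity),
    label = if (is.null(a$query$label)) NA_character_ else
      as.character(a$query$label),
    status = a$status, position = a$position,
    all_positions = paste(a$all_positions, collapse = ";"),
    categories = paste(a$categories, collapse = "+"),
    n_evidences = nrow(a$matched_evidence),
    proteases = paste(sort(unique(a$protease_matches$protease_accession)),
                      collapse = ";"),
    features_n_terminal = fmt_feat(a$features_n_terminal),
    features_c_terminal = fmt_feat(a$features_c_terminal),
    features_at_position = fmt_feat(a$features_at_position),
    stringsAsFactors = FALSE)
}

#' Run the full terminus-annotation analysis on a query list
#'
#' Executes locate, classify and feature annotation for every query peptide,
#' then the summary statistics: protease enrichment table, category-overlap
#' (Venn) counts, substrate-by-protease matrix and the sequence logo.
#' Row-level problems (unknown accession, unlocatable peptide) are recorded
#' in the annotation table's status column; the run never aborts on a single
#' bad row. Deterministic given inputs and options.
#'
#' @param query_list data frame with columns accession, peptide,
#'   terminus_type and optionally quantity, label (see
#'   \code{\link{read_query_list}})
#' @param kb a validated \code{termikit_kb}
#' @param window residue window (0..10) for evidence and cleavage matching
#' @param span residues per side in the sequence logo
#' @param alpha probability cutoff for logo significance
#' @param background optional residue background for the logo
#' @param out_dir optional directory; when given, all report files are
#'   written there (see \code{\link{write_topfinder_report}})
#' @return object of class \code{topfinder_result}
#' @export
run_topfinder <- function(query_list, kb, window = 0L, span = 8L,
                          alpha = 0.05, background = NULL, out_dir = NULL) {
  stopifnot(inherits(kb, "termikit_kb"))
  query_list <- as.data.frame(query_list)
  anns <- vector("list", nrow(query_list))
  for (i in seq_len(nrow(query_list))) {
    q <- query_list[i, , drop = FALSE]
    j <- match(q$accession, kb$proteins$accession)
    prot <- if (is.na(j)) NULL else kb$proteins[j, , drop = FALSE]
    anns[[i]] <- tryCatch({
      a <- locate_terminus(q, prot)
      a <- classify_terminus(a, kb, window = window)
      annotate_features(a, kb)
    }, error = function(e) {
      # a malformed row (e.g. too-short peptide) is reported, never fatal
      a <- locate_terminus(list(accession = as.character(q$accession),
                                peptide = "XXXX", terminus_type = "N",
                                quantity = q$quantity, label = q$label), NULL)
      a$query$peptide <- as.character(q$peptide)
      a$query$terminus_type <- as.character(q$terminus_type)
      a$status <- paste0("error: ", conditionMessage(e))
      a
    })
  }
  annotation_table <- if (length(anns) > 0)
    do.call(rbind, lapply(anns, annotation_to_row)) else
      annotation_to_row(locate_terminus(
        list(accession = "x", peptide = "XXXX", terminus_type = "N")))[0, ]
  res <- structure(list(
    annotations = anns,
    annotation_table = annotation_table,
    enrichment = protease_enrichment_table(anns, kb),
    venn = venn_counts(anns),
    matrix = substrate_protease_matrix(anns),
    logo = ice_logo(anns, kb, span = span, alpha = alpha,
                    background = background),
    options = list(window = window, span = span, alpha = alpha)),
    class = "topfinder_result")
  if (!is.null(out_dir)) write_topfinder_report(res, out_dir)
  res
}

#' @export
print.topfinder_result <- function(x, ...) {
  st <- table(factor(vapply(x$annotations, function(a) a$status, character(1)),
                     levels = c("located", "not_found", "ambiguous",
                                "unknown_protein")))
  cat(sprintf("<topfinder result> %d quer%s\n", length(x$annotations),
              if (length(x$annotations) == 1) "y" else "ies"))
  cat(sprintf("  located %d, not_found %d, ambiguous %d, unknown_protein %d\n",
              st[["located"]], st[["not_found"]], st[["ambiguous"]],
              st[["unknown_protein"]]))
  cat(sprintf("  cleavage-derived termini: %d; identified proteases: %d\n",
              if (nrow(x$enrichment) > 0) x$enrichment$n[1] else 0L,
              nrow(x$enrichment)))
  if (nrow(x$enrichment) > 0) {
    cat("  top proteases by p-value:\n")
    top <- head(x$enrichment, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s (%s): k=%d/%d, K=%d/%d, fold=%.2f, q=%.3g\n",
                  top$protease_name[i], top$protease_accession[i], top$k[i],
                  top$n[i], top$K[i], top$M[i], top$fold_enrichment[i],
                  top$q_value[i]))
  }
  invisible(x)
}

#' @export
#' @method summary topfinder_result
summary.topfinder_result <- function(object, ...) {
  print(object)
  if (nrow(object$venn) > 0) {
    cat("  category subsets:\n")
    for (i in seq_len(nrow(object$venn)))
      cat(sprintf("    %-40s %d\n",
                  ifelse(nzchar(object$venn$subset[i]), object$venn$subset[i],
                         "(none)"), object$venn$count[i]))
  }
  invisible(object)
}

round_half_up <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

format_sci3 <- function(p) toupper(formatC(p, format = "e", digits = 2))

#' Write the report files of a terminus-annotation run
#'
#' Emits annotation.tsv (one row per query), enrichment.tsv (count columns,
#' folds rounded half-up to 2 decimals, p/q in 3-significant-figure
#' scientific notation), venn.tsv, matrix.tsv and logo.tsv.
#'
#' @param result a \code{topfinder_result}
#' @param out_dir output directory (created if absent)
#' @export
write_topfinder_report <- function(result, out_dir) {
  stopifnot(inherits(result, "topfinder_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "")
  tsv(result$annotation_table, "annotation.tsv")
  enr <- result$enrichment
  enr_out <- data.frame(
    protease_name = enr$protease_name,
    protease_accession = enr$protease_accession,
    list_count = enr$k, list_count_total = enr$n,
    db_count = enr$K, db_count_total = enr$M,
    fold_enrichment = sprintf("%.2f", round_half_up(enr$fold_enrichment, 2)),
    fold_coverage = sprintf("%.2f", round_half_up(enr$fold_coverage, 2)),
    p_value = format_sci3(enr$p_value), q_value = format_sci3(enr$q_value),
    stringsAsFactors = FALSE)
  tsv(enr_out, "enrichment.tsv")
  tsv(result$venn, "venn.tsv")
  m <- result$matrix
  mat_df <- data.frame(terminus = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE)
  tsv(mat_df, "matrix.tsv")
  tsv(logo_to_table(result$logo), "logo.tsv")
  invisible(out_dir)
}
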