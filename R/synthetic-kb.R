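# Seeded generator of synthetic knowledgebases and terminomics query lists.
# The generator plays the role of the curated database in tests: random
# protein sequences, isoforms differing by one internal indel, canonical
# terminus evidences, protease cleavage events (with a controlled fraction of
# sites shared between two proteases, as for the caspase-3/-7 overlap seen in
# curated data), inhibitor->protease events, and query lists with a planted
# over-represented protease.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Parameters for the synthetic knowledgebase generator
#'
#' @param n_proteins number of canonical proteins
#' @param n_proteases number of proteins acting as proteases (the first
#'   \code{n_proteases} accessions)
#' @param n_inhibitors number of proteins acting as inhibitors (the next
#'   \code{n_inhibitors} accessions)
#' @param mean_protein_length mean sequence length in residues (lengths are
#'   uniform within +/-20\%)
#' @param n_cleavages number of distinct (protease, substrate, P1) cleavage
#'   events
#' @param n_inhibitions number of distinct inhibitor->protease events
#' @param isoform_rate probability that a canonical protein carries one
#'   isoform differing by a single internal indel
#' @param indel_length_range length range (residues) of the isoform indel
#' @param shared_site_rate fraction of cleavage events that re-use an existing
#'   (substrate, P1) site under a second protease
#' @param residue_freqs optional named vector of residue frequencies over the
#'   20 amino acids (default uniform)
#' @param species species label stamped on proteins and cleavages
#' @param seed integer seed; the same seed yields a byte-identical
#'   knowledgebase
#' @return object of class \code{synth_params}
#' @export
synth_params <- function(n_proteins = 100L, n_proteases = 10L,
                         n_inhibitors = 5L, mean_protein_length = 300L,
                         n_cleavages = 300L, n_inhibitions = 10L,
                         isoform_rate = 0, indel_length_range = c(1L, 15L),
                         shared_site_rate = 0.1, residue_freqs = NULL,
                         species = "human", seed = 1L) {
  stopifnot(n_proteins >= 0, n_proteases >= 0, n_inhibitors >= 0,
            n_proteases + n_inhibitors <= max(n_proteins, 0),
            mean_protein_length >= 60 || n_proteins == 0,
            n_cleavages >= 0, n_inhibitions >= 0,
            isoform_rate >= 0, isoform_rate <= 1,
            shared_site_rate >= 0, shared_site_rate <= 1,
            length(indel_length_range) == 2,
            indel_length_range[1] >= 1,
            indel_length_range[1] <= indel_length_range[2],
            is.numeric(seed), length(seed) == 1)
  if (!is.null(residue_freqs)) {
    stopifnot(setequal(names(residue_freqs), AA20), all(residue_freqs > 0))
    residue_freqs <- residue_freqs[AA20] / sum(residue_freqs)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_proteases = as.integer(n_proteases),
                 n_inhibitors = as.integer(n_inhibitors),
                 mean_protein_length = as.integer(mean_protein_length),
                 n_cleavages = as.integer(n_cleavages),
                 n_inhibitions = as.integer(n_inhibitions),
                 isoform_rate = isoform_rate,
                 indel_length_range = as.integer(indel_length_range),
                 shared_site_rate = shared_site_rate,
                 residue_freqs = residue_freqs, species = species,
                 seed = as.integer(seed)),
            class = "synth_params")
}

random_sequence <- function(len, freqs = NULL) {
  prob <- if (is.null(freqs)) NULL else freqs[AA20]
  paste(sample(AA20, len, replace = TRUE, prob = prob), collapse = "")
}

#' Generate a synthetic knowledgebase
#'
#' Builds a knowledgebase that passes \code{\link{validate_kb}}: random
#' protein sequences, canonical N/C terminus evidences at position 1 and the
#' sequence length, distinct cleavage events with P1 placed at least 20
#' residues from either sequence end (so every 20-residue context and
#' neo-terminal peptide is extractable), a controlled fraction of sites shared
#' between two proteases, inhibitor->protease events, two domain features per
#' protein, and (at \code{isoform_rate} > 0) isoforms derived from the
#' canonical sequence by one internal indel at least 25 residues from both
#' termini.
#'
#' @param params a \code{\link{synth_params}} object
#' @return a validated \code{termikit_kb}
#' @export
generate_kb <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  with_seed(p$seed, {
    if (p$n_proteins == 0) return(kb())
    lens <- as.integer(round(runif(p$n_proteins, 0.8 * p$mean_protein_length,
                                   1.2 * p$mean_protein_length)))
    lens <- pmax(lens, 60L)
    acc <- sprintf("SP%04d", seq_len(p$n_proteins))
    seqs <- vapply(lens, random_sequence, character(1), freqs = p$residue_freqs)
    proteins <- data.frame(accession = acc,
                           name = sprintf("PROT%d", seq_len(p$n_proteins)),
                           species = p$species, is_canonical = TRUE,
                           parent_accession = NA_character_,
                           sequence = seqs, stringsAsFactors = FALSE)

    # isoforms: one internal indel (1-15 residues) at least 25 residues from
    # both termini, so every 20-residue terminal/cleavage context outside the
    # indel remains uniquely locatable
    iso_rows <- list()
    has_iso <- runif(p$n_proteins) < p$isoform_rate
    for (i in which(has_iso)) {
      len <- lens[i]
      d <- p$indel_length_range[1] +
        sample.int(p$indel_length_range[2] - p$indel_length_range[1] + 1L,
                   1L) - 1L
      op <- sample(c("del", "ins"), 1L)
      if (op == "del") {
        lo <- 26L; hi <- len - 25L - d + 1L
        if (hi < lo) next
        st <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        iseq <- paste0(substr(seqs[i], 1L, st - 1L),
                       substr(seqs[i], st + d, len))
      } else {
        lo <- 26L; hi <- len - 25L
        if (hi < lo) next
        st <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        iseq <- paste0(substr(seqs[i], 1L, st),
                       random_sequence(d, p$residue_freqs),
                       substr(seqs[i], st + 1L, len))
      }
      iso_rows[[length(iso_rows) + 1]] <- data.frame(
        accession = paste0(acc[i], "-2"), name = sprintf("PROT%d iso", i),
        species = p$species, is_canonical = FALSE, parent_accession = acc[i],
        sequence = iseq, stringsAsFactors = FALSE)
    }
    if (length(iso_rows) > 0)
      proteins <- rbind(proteins, do.call(rbind, iso_rows))

    termini <- data.frame(
      protein_accession = rep(proteins$accession, 2L),
      terminus_type = rep(c("N", "C"), each = nrow(proteins)),
      position = c(rep(1L, nrow(proteins)), nchar(proteins$sequence)),
      category = "canonical", source_id = "synthetic:canonical",
      confidence = NA_real_, stringsAsFactors = FALSE)

    features <- do.call(rbind, lapply(seq_len(p$n_proteins), function(i) {
      st <- sort(sample.int(lens[i] - 30L, 2L))
      data.frame(protein_accession = acc[i], kind = "domain", start = st,
                 end = pmin(st + sample(10:40, 2L, replace = TRUE), lens[i]),
                 description = sprintf("synthetic domain %d", seq_along(st)),
                 stringsAsFactors = FALSE)
    }))

    cleavages <- kb_template("cleavages")
    if (p$n_cleavages > 0) {
      if (p$n_proteases < 1) stop("n_cleavages > 0 requires n_proteases >= 1")
      pos_per_sub <- pmax(lens - 40L, 0L)
      capacity <- p$n_proteases * sum(pos_per_sub) -
        sum(pos_per_sub[seq_len(p$n_proteases)])
      if (p$n_cleavages > capacity)
        stop(sprintf("infeasible parameters: %d cleavages requested but only %d distinct sites available",
                     p$n_cleavages, capacity))
      n_shared <- if (p$n_proteases >= 2)
        as.integer(round(p$n_cleavages * p$shared_site_rate)) else 0L
      n_main <- p$n_cleavages - n_shared
      if (n_main == 0L && n_shared > 0L) {
        n_main <- 1L
        n_shared <- n_shared - 1L
      }
      keys <- character(0)
      rows <- vector("list", p$n_cleavages)
      n_done <- 0L
      attempts <- 0L
      while (n_done < n_main) {
        attempts <- attempts + 1L
        if (attempts > 200L * p$n_cleavages + 1000L)
          stop("infeasible parameters: could not place distinct cleavage sites")
        pi <- sample.int(p$n_proteases, 1L)
        si <- sample.int(p$n_proteins, 1L)
        if (si == pi || pos_per_sub[si] < 1L) next
        p1 <- sample.int(pos_per_sub[si], 1L) + 20L
        key <- paste(pi, si, p1, sep = "\r")
        if (key %in% keys) next
        keys <- c(keys, key)
        n_done <- n_done + 1L
        rows[[n_done]] <- c(pi, si, p1)
      }
      while (n_done < p$n_cleavages) {
        attempts <- attempts + 1L
        if (attempts > 200L * p$n_cleavages + 1000L)
          stop("infeasible parameters: could not place shared cleavage sites")
        base <- rows[[sample.int(max(n_main, 1L), 1L)]]
        pi <- sample.int(p$n_proteases, 1L)
        if (pi == base[1] || pi == base[2]) next
        key <- paste(pi, base[2], base[3], sep = "\r")
        if (key %in% keys) next
        keys <- c(keys, key)
        n_done <- n_done + 1L
        rows[[n_done]] <- c(pi, base[2], base[3])
      }
      m <- do.call(rbind, rows)
      cleavages <- data.frame(protease_accession = acc[m[, 1]],
                              substrate_accession = acc[m[, 2]],
                              p1_position = as.integer(m[, 3]),
                              evidence_source = "synthetic:cleavage",
                              species = p$species, stringsAsFactors = FALSE)
    }

    inhibitions <- kb_template("inhibitions")
    if (p$n_inhibitions > 0) {
      if (p$n_inhibitors < 1 || p$n_proteases < 1)
        stop("n_inhibitions > 0 requires inhibitors and proteases")
      if (p$n_inhibitions > p$n_inhibitors * p$n_proteases)
        stop("infeasible parameters: more inhibitions than inhibitor-protease pairs")
      pairs <- expand.grid(inh = seq_len(p$n_inhibitors),
                           pro = seq_len(p$n_proteases))
      sel <- pairs[sample.int(nrow(pairs), p$n_inhibitions), , drop = FALSE]
      inhibitions <- data.frame(
        inhibitor_accession = acc[p$n_proteases + sel$inh],
        protease_accession = acc[sel$pro],
        evidence_source = "synthetic:inhibition", stringsAsFactors = FALSE)
    }

    out <- kb(proteins = proteins, features = features, termini = termini,
              cleavages = cleavages, inhibitions = inhibitions)
    stop_on_violations(validate_kb(out), "generate_kb")
    out
  })
}

#' Description of a planted enrichment signal for query-list generation
#'
#' @param protease_accession the protease whose neo-termini are planted
#' @param list_size number of query peptides
#' @param fraction_from_protease fraction of peptides drawn from the planted
#'   protease's cleavage sites
#' @param ragging_jitter maximum residue offset applied to planted start
#'   positions (0 = exact neo-termini)
#' @param seed integer seed for the draw
#' @return object of class \code{planted_signal}
#' @export
planted_signal <- function(protease_accession, list_size = 100L,
                           fraction_from_protease = 0.5, ragging_jitter = 0L,
                           seed = 1L) {
  stopifnot(is.character(protease_accession), list_size >= 0,
            fraction_from_protease >= 0, fraction_from_protease <= 1,
            ragging_jitter >= 0)
  structure(list(protease_accession = protease_accession,
                 list_size = as.integer(list_size),
                 fraction_from_protease = fraction_from_protease,
                 ragging_jitter = as.integer(ragging_jitter),
                 seed = as.integer(seed)),
            class = "planted_signal")
}

#' Generate a query list of terminal peptides with a planted protease signal
#'
#' Emulates a TAILS-style N-terminomics peptide list: a fraction of peptides
#' are the 10-residue windows starting at P1+1 of randomly chosen cleavage
#' sites of the planted protease (optionally offset by ragging jitter); the
#' remainder are canonical protein starts or random internal positions. Every
#' peptide occurs verbatim in its protein's sequence.
#'
#' @param kb a validated \code{termikit_kb}
#' @param signal a \code{\link{planted_signal}}
#' @return data frame with columns accession, peptide, terminus_type,
#'   quantity, label
#' @export
generate_query_list <- function(kb, signal) {
  stopifnot(inherits(kb, "termikit_kb"), inherits(signal, "planted_signal"))
  clv <- kb$cleavages[kb$cleavages$protease_accession ==
                        signal$protease_accession, , drop = FALSE]
  if (signal$list_size > 0 && signal$fraction_from_protease > 0 &&
      nrow(clv) == 0)
    stop(sprintf("planted protease '%s' has no cleavages in the knowledgebase",
                 signal$protease_accession))
  with_seed(signal$seed, {
    n <- signal$list_size
    if (n == 0)
      return(data.frame(accession = character(), peptide = character(),
                        terminus_type = character(), quantity = numeric(),
                        label = character(), stringsAsFactors = FALSE))
    n_sig <- as.integer(round(n * signal$fraction_from_protease))
    canon <- kb$proteins[kb$proteins$is_canonical, , drop = FALSE]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (i <= n_sig) {
        ev <- clv[sample.int(nrow(clv), 1L), ]
        seq <- kb_sequence(kb, ev$substrate_accession)
        start <- ev$p1_position + 1L
        if (signal$ragging_jitter > 0)
          start <- start + sample(seq(-signal$ragging_jitter,
                                      signal$ragging_jitter), 1L)
        start <- min(max(start, 1L), nchar(seq) - 9L)
        accession <- ev$substrate_accession
      } else {
        j <- sample.int(nrow(canon), 1L)
        seq <- canon$sequence[j]
        accession <- canon$accession[j]
        start <- if (runif(1) < 0.5) 1L else
          sample.int(nchar(seq) - 10L, 1L) + 1L
      }
      rows[[i]] <- data.frame(accession = accession,
                              peptide = substr(seq, start, start + 9L),
                              terminus_type = "N",
                              quantity = round(rnorm(1), 3),
                              label = sprintf("pep%04d", i),
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Read a query list of terminal peptides from TSV
#'
#' Expected columns (header required): accession, peptide, terminus_type
#' (N or C), and optionally quantity (e.g. a log2 ratio) and label.
#'
#' @param path TSV file path
#' @return data frame with columns accession, peptide, terminus_type,
#'   quantity, label
#' @export
read_query_list <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", na.strings = "",
                   stringsAsFactors = FALSE)
  need <- c("accession", "peptide", "terminus_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("query list %s: missing column(s) %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (is.null(df$quantity)) df$quantity <- NA_character_
  if (is.null(df$label)) df$label <- NA_character_
  df$quantity <- as.numeric(df$quantity)
  df[, c("accession", "peptide", "terminus_type", "quantity", "label")]
}

#' Write a query list of terminal peptides to TSV
#'
#' @param query_list data frame as returned by
#'   \code{\link{generate_query_list}} or \code{\link{read_query_list}}
#' @param path output TSV path
#' @export
write_query_list <- function(query_list, path) {
  write.table(query_list, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
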