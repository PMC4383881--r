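test_that("terminal peptides are located by unique exact substring match", {
  s <- rand_seq(120, seed = 20)
  prot <- data.frame(accession = "P1", sequence = s, stringsAsFactors = FALSE)
  a <- locate_terminus(list(accession = "P1", peptide = substr(s, 1, 10),
                            terminus_type = "N"), prot)
  expect_equal(a$status, "located")
  expect_equal(a$position, 1L)
  a45 <- locate_terminus(list(accession = "P1",
                              peptide = substr(s, 45, 54),
                              terminus_type = "N"), prot)
  expect_equal(a45$position, 45L)
  # C-terminal peptide: position is the last residue of the hit
  ac <- locate_terminus(list(accession = "P1", peptide = substr(s, 45, 54),
                             terminus_type = "C"), prot)
  expect_equal(ac$position, 54L)
  aun <- locate_terminus(list(accession = "NOPE", peptide = "AAAA",
                              terminus_type = "N"), NULL)
  expect_equal(aun$status, "unknown_protein")
})

test_that("repeated peptides are flagged ambiguous with every hit recorded", {
  polyA <- paste0(paste(rep("A", 30), collapse = ""), rand_seq(40, seed = 21))
  prot <- data.frame(accession = "P1", sequence = polyA,
                     stringsAsFactors = FALSE)
  a <- locate_terminus(list(accession = "P1", peptide = "AAAA",
                            terminus_type = "N"), prot)
  expect_equal(a$status, "ambiguous")
  expect_equal(a$all_positions, naive_match("AAAA", polyA))
})

test_that("origin classification follows the evidence and the P1 convention", {
  k <- toy_kb()
  sub1 <- k$proteins[k$proteins$accession == "SUB1", ]
  # canonical evidence at 1, window 0
  a1 <- classify_terminus(locate_terminus(list(
    accession = "SUB1", peptide = substr(sub1$sequence, 1, 10),
    terminus_type = "N"), sub1), k, window = 0)
  expect_equal(a1$categories, "canonical")
  # N-terminus at t = P1 + 1 matches the cleavage at window 0
  a51 <- classify_terminus(locate_terminus(list(
    accession = "SUB1", peptide = substr(sub1$sequence, 51, 60),
    terminus_type = "N"), sub1), k, window = 0)
  expect_equal(a51$categories, "cleaved")
  expect_equal(a51$protease_matches$protease_accession, "PRT1")
  # C-terminus at t = P1 matches too
  a50c <- classify_terminus(locate_terminus(list(
    accession = "SUB1", peptide = substr(sub1$sequence, 41, 50),
    terminus_type = "C"), sub1), k, window = 0)
  expect_true("cleaved" %in% a50c$categories)
})

test_that("the ragging window enlarges but never shrinks the category set", {
  k <- toy_kb()
  sub1 <- k$proteins[k$proteins$accession == "SUB1", ]
  # N-terminus at 53: implied P1 = 52, cleavage at 50 -> only window >= 2
  a <- locate_terminus(list(accession = "SUB1",
                            peptide = substr(sub1$sequence, 53, 62),
                            terminus_type = "N"), sub1)
  expect_equal(classify_terminus(a, k, window = 0)$categories, character(0))
  expect_equal(classify_terminus(a, k, window = 2)$categories, "cleaved")
  # brute-force scan: every cleavage within the window is matched
  for (w in 0:10) {
    got <- classify_terminus(a, k, window = w)$protease_matches
    want <- k$cleavages[k$cleavages$substrate_accession == "SUB1" &
                          abs(k$cleavages$p1_position - (53 - 1)) <= w, ]
    expect_equal(nrow(got), nrow(want), info = paste("window", w))
  }
  # monotonicity across windows for many synthetic termini
  ksyn <- generate_kb(synth_params(n_proteins = 20, n_proteases = 4,
                                   n_inhibitors = 2, n_cleavages = 40,
                                   n_inhibitions = 2, seed = 30))
  ql <- generate_query_list(ksyn, planted_signal("SP0001", 20, 1, seed = 31))
  for (i in seq_len(nrow(ql))) {
    prot <- ksyn$proteins[ksyn$proteins$accession == ql$accession[i], ]
    a <- locate_terminus(ql[i, ], prot)
    prev <- character(0)
    for (w in c(0, 2, 5, 10)) {
      cats <- classify_terminus(a, ksyn, window = w)$categories
      expect_true(all(prev %in% cats))
      prev <- cats
    }
  }
})

test_that("features partition three ways around the terminus", {
  k <- toy_kb()
  sub1 <- k$proteins[k$proteins$accession == "SUB1", ]
  mk <- function(pos) annotate_features(classify_terminus(locate_terminus(
    list(accession = "SUB1",
         peptide = substr(sub1$sequence, pos, pos + 9), terminus_type = "N"),
    sub1), k), k)
  a60 <- mk(60)   # domain 10..40 lost, domain 120..180 retained
  expect_equal(nrow(a60$features_n_terminal), 1)
  expect_equal(nrow(a60$features_c_terminal), 1)
  expect_equal(nrow(a60$features_at_position), 0)
  a30 <- mk(30)   # inside domain 10..40
  expect_equal(a30$features_at_position$start, 10L)
  # brute-force interval check on synthetic features
  set.seed(32)
  for (r in 1:10) {
    pos <- sample(5:190, 1)
    a <- mk(pos)
    ft <- k$features[k$features$protein_accession == "SUB1", ]
    expect_equal(nrow(a$features_n_terminal), sum(ft$end < pos))
    expect_equal(nrow(a$features_c_terminal), sum(ft$start > pos))
    expect_equal(nrow(a$features_at_position),
                 sum(ft$start <= pos & ft$end >= pos))
  }
})

test_that("the enrichment tail probability matches the published table rows", {
  expect_equal(signif(fisher_enrichment_p(4, 129, 4, 1265), 3), 3.65e-3)
  expect_equal(signif(fisher_enrichment_p(1, 129, 1, 1265), 3), 1.77e-1)
  expect_equal(fisher_enrichment_p(0, 12, 5, 100), 1.0)
})

test_that("the enrichment tail equals fixed-margin enumeration on small tables", {
  set.seed(33)
  for (r in 1:200) {
    n <- sample(1:20, 1)
    M <- sample(1:(40 - n), 1)
    k <- sample(0:n, 1)
    K <- sample(0:M, 1)
    expect_equal(fisher_enrichment_p(k, n, K, M), fisher_oracle(k, n, K, M),
                 tolerance = 1e-12, info = sprintf("k=%d n=%d K=%d M=%d",
                                                   k, n, K, M))
  }
  expect_error(fisher_enrichment_p(5, 4, 1, 10), "require")
})

test_that("BH adjustment matches the step-up definition and its invariants", {
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(34)
  for (r in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("enrichment rows satisfy their algebraic identities", {
  # fold_enrichment * (K/M) * n = k and fold_coverage * K = k
  rows <- list(c(68, 129, 537, 1265), c(16, 129, 58, 1265),
               c(4, 129, 4, 1265), c(2, 129, 16, 1265))
  for (r in rows) {
    st <- enrichment_stats(r[1], r[2], r[3], r[4])
    expect_equal(st$fold_enrichment * (r[3] / r[4]) * r[2], r[1])
    expect_equal(st$fold_coverage * r[3], r[1])
  }
})

test_that("the enrichment table counts termini and sites per the background definition", {
  # two proteases; one shared site; three query termini, two cleaved
  set.seed(35)
  seqs <- vapply(1:4, function(i) rand_seq(100), character(1))
  accs <- c("PA", "PB", "S1", "S2")
  k <- kb(proteins = data.frame(accession = accs, name = accs,
                                species = "human", is_canonical = TRUE,
                                parent_accession = NA_character_,
                                sequence = seqs, stringsAsFactors = FALSE),
          cleavages = data.frame(
            protease_accession = c("PA", "PB", "PA", "PB"),
            substrate_accession = c("S1", "S1", "S2", "S2"),
            p1_position = c(30L, 30L, 40L, 60L),
            evidence_source = "assay", species = "human",
            stringsAsFactors = FALSE))
  ql <- data.frame(
    accession = c("S1", "S2", "S2"),
    peptide = c(substr(seqs[3], 31, 40), substr(seqs[4], 41, 50),
                substr(seqs[4], 5, 14)),
    terminus_type = "N", stringsAsFactors = FALSE)
  res <- run_topfinder(ql, k)
  enr <- res$enrichment
  expect_equal(enr$n[1], 2)           # two cleaved termini
  expect_equal(enr$M[1], 3)           # sites (S1,30) (S2,40) (S2,60); shared counts once
  expect_equal(enr$k[enr$protease_accession == "PA"], 2)
  expect_equal(enr$k[enr$protease_accession == "PB"], 1)  # shared site at S1:30
  expect_equal(enr$K[enr$protease_accession == "PA"], 2)
  expect_equal(enr$K[enr$protease_accession == "PB"], 2)
  # degenerate one-protease background: k=n, K=M -> fold 1, p 1
  st <- enrichment_stats(5, 5, 9, 9)
  expect_equal(st$fold_enrichment, 1)
  expect_equal(st$p_value, 1)
})

test_that("venn subset counts are exact and sum to the located termini", {
  k <- toy_kb()
  sub1 <- k$proteins[k$proteins$accession == "SUB1", ]
  anns <- list(
    classify_terminus(locate_terminus(list(
      accession = "SUB1", peptide = substr(sub1$sequence, 1, 10),
      terminus_type = "N"), sub1), k),
    classify_terminus(locate_terminus(list(
      accession = "SUB1", peptide = substr(sub1$sequence, 51, 60),
      terminus_type = "N"), sub1), k),
    classify_terminus(locate_terminus(list(
      accession = "SUB1", peptide = substr(sub1$sequence, 70, 79),
      terminus_type = "N"), sub1), k))
  v <- venn_counts(anns)
  expect_equal(sum(v$count), 3)
  expect_setequal(v$subset, c("canonical", "cleaved", ""))
  expect_equal(venn_counts(list()),
               data.frame(subset = character(), count = integer(),
                          stringsAsFactors = FALSE))
  # brute-force tally on a synthetic list
  ksyn <- generate_kb(synth_params(n_proteins = 20, n_proteases = 4,
                                   n_inhibitors = 2, n_cleavages = 40,
                                   n_inhibitions = 2, seed = 36))
  ql <- generate_query_list(ksyn, planted_signal("SP0001", 30, 0.5,
                                                 seed = 37))
  res <- run_topfinder(ql, ksyn)
  v <- venn_counts(res$annotations)
  cat_order <- c("canonical", "alt_splicing", "alt_translation", "cleaved",
                 "experimental")
  tally <- table(vapply(Filter(function(a) a$status == "located",
                               res$annotations), function(a)
    paste(a$categories[order(match(a$categories, cat_order))],
          collapse = "+"), character(1)))
  for (i in seq_len(nrow(v)))
    expect_equal(v$count[i],
                 unname(as.integer(tally[match(v$subset[i], names(tally))])))
  expect_equal(sum(v$count),
               sum(vapply(res$annotations, function(a)
                 a$status == "located", logical(1))))
})

test_that("the substrate-protease matrix reflects attribution marginals", {
  # one terminus matched by two proteases -> one row with two 1-cells
  set.seed(38)
  seqs <- rand_seq(100)
  k <- kb(proteins = data.frame(
            accession = c("PA", "PB", "S1"), name = "x", species = "human",
            is_canonical = TRUE, parent_accession = NA_character_,
            sequence = c(rand_seq(80), rand_seq(80), seqs),
            stringsAsFactors = FALSE),
          cleavages = data.frame(
            protease_accession = c("PA", "PB"), substrate_accession = "S1",
            p1_position = 30L, evidence_source = "assay", species = "human",
            stringsAsFactors = FALSE))
  ql <- data.frame(accession = "S1", peptide = substr(seqs, 31, 40),
                   terminus_type = "N", stringsAsFactors = FALSE)
  res <- run_topfinder(ql, k)
  m <- res$matrix
  expect_equal(dim(m), c(1, 2))
  expect_equal(unname(rowSums(m)), 2)
  expect_equal(rownames(m), "S1:31")
  # marginal-sum oracle on a synthetic list
  ksyn <- generate_kb(synth_params(n_proteins = 20, n_proteases = 4,
                                   n_inhibitors = 2, n_cleavages = 50,
                                   n_inhibitions = 2, seed = 39))
  ql <- generate_query_list(ksyn, planted_signal("SP0001", 25, 0.8,
                                                 seed = 40))
  res <- run_topfinder(ql, ksyn)
  m <- res$matrix
  per_prot <- integer(0)
  for (a in res$annotations)
    if (a$status == "located" && nrow(a$protease_matches) > 0) {
      lbl <- paste0(a$query$accession, ":", a$position)
      for (p in unique(a$protease_matches$protease_accession))
        per_prot[paste(lbl, p)] <- 1L
    }
  expect_equal(sum(m), length(per_prot))
  expect_true(all(diff(rowSums(m)) <= 0) || nrow(m) < 2 ||
                !is.unsorted(-rowSums(m)))
  expect_equal(substrate_protease_matrix(list()), matrix(integer(0), 0, 0))
})

test_that("the sequence logo reports frequencies against the background", {
  # all sequences identical: frequency 1 at every offset, significant when
  # the background gives that residue less than 1
  s <- rand_seq(100, seed = 43)
  k <- kb(proteins = data.frame(
    accession = "P1", name = "x", species = "human", is_canonical = TRUE,
    parent_accession = NA_character_, sequence = s, stringsAsFactors = FALSE))
  anns <- lapply(1:5, function(i) {
    a <- locate_terminus(list(accession = "P1",
                              peptide = substr(s, 21, 30),
                              terminus_type = "N"),
                         k$proteins[1, , drop = FALSE])
    classify_terminus(a, k, 0)
  })
  logo <- ice_logo(anns, k, span = 4, alpha = 0.05,
                   background = setNames(rep(1 / 20, 20), aa20))
  expect_equal(logo$n_sequences, 5)
  expect_true(all(rowSums(logo$frequencies) == 1))
  expect_true(all(logo$frequencies[logo$frequencies > 0] == 1))
  expect_true(all(logo$significant[logo$counts == 5]))
  # alpha = 1 flags every present residue
  logo1 <- ice_logo(anns, k, span = 4, alpha = 1,
                    background = setNames(rep(1 / 20, 20), aa20))
  expect_true(all(logo1$significant[logo1$counts > 0]))
  # termini carrying only translational categories are excluded
  a_can <- classify_terminus(locate_terminus(list(
    accession = "P1", peptide = substr(s, 1, 10), terminus_type = "N"),
    k$proteins[1, , drop = FALSE]), kb(proteins = k$proteins,
      termini = data.frame(protein_accession = "P1", terminus_type = "N",
                           position = 1L, category = "canonical",
                           source_id = "u", confidence = NA_real_,
                           stringsAsFactors = FALSE)), 0)
  logo2 <- ice_logo(c(anns, list(a_can)), k, span = 4)
  expect_equal(logo2$n_sequences, 5)
})

test_that("a full run is deterministic and never aborts on bad rows", {
  k <- generate_kb(synth_params(n_proteins = 25, n_proteases = 4,
                                n_inhibitors = 2, n_cleavages = 50,
                                n_inhibitions = 3, seed = 41))
  ql <- generate_query_list(k, planted_signal("SP0001", 30, 0.5, seed = 42))
  ql <- rbind(ql, data.frame(accession = c("MISSING", "SP0002"),
                             peptide = c("AAAAAAA", "AAA"),
                             terminus_type = "N", quantity = NA,
                             label = c("bad1", "bad2")))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_topfinder(ql, k, out_dir = d1)
  run_topfinder(ql, k, out_dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  tab <- res$annotation_table
  expect_equal(tab$status[tab$label == "bad1"], "unknown_protein")
  expect_match(tab$status[tab$label == "bad2"], "error")
  # empty query list: empty tables, no error
  res0 <- run_topfinder(ql[0, ], k)
  expect_equal(nrow(res0$annotation_table), 0)
  expect_equal(nrow(res0$enrichment), 0)
})

test_that("a planted protease dominates the enrichment ranking", {
  k <- generate_kb(synth_params(seed = 50))
  ql <- generate_query_list(k, planted_signal("SP0003", 100, 0.5, seed = 51))
  res <- run_topfinder(ql, k)
  enr <- res$enrichment
  expect_equal(enr$protease_accession[which.min(enr$q_value)], "SP0003")
  expect_lt(enr$q_value[enr$protease_accession == "SP0003"], 0.05)
})
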