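# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (enumeration, brute-force scans) and never share code
# with the implementation paths they check.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa20, len, replace = TRUE), collapse = "")
}

# A small handcrafted knowledgebase: one protease (PRT1), one inhibitor
# (INH1), two substrates; one cleavage of SUB1 at P1=50, one inhibition of
# PRT1 by INH1; canonical termini throughout; two features on SUB1.
toy_kb <- function() {
  set.seed(42)
  seqs <- c(PRT1 = rand_seq(120), INH1 = rand_seq(110),
            SUB1 = rand_seq(200), SUB2 = rand_seq(150))
  kb(proteins = data.frame(
       accession = names(seqs), name = paste0("protein ", names(seqs)),
       species = "human", is_canonical = TRUE,
       parent_accession = NA_character_, sequence = unname(seqs),
       stringsAsFactors = FALSE),
     termini = data.frame(
       protein_accession = rep(names(seqs), 2),
       terminus_type = rep(c("N", "C"), each = 4),
       position = c(rep(1L, 4), nchar(unname(seqs))),
       category = "canonical", source_id = "uniprot",
       confidence = NA_real_, stringsAsFactors = FALSE),
     cleavages = data.frame(
       protease_accession = "PRT1", substrate_accession = "SUB1",
       p1_position = 50L, evidence_source = "assay", species = "human",
       stringsAsFactors = FALSE),
     inhibitions = data.frame(
       inhibitor_accession = "INH1", protease_accession = "PRT1",
       evidence_source = "assay", stringsAsFactors = FALSE),
     features = data.frame(
       protein_accession = c("SUB1", "SUB1"), kind = c("domain", "domain"),
       start = c(10L, 120L), end = c(40L, 180L),
       description = c("dom A", "dom B"), stringsAsFactors = FALSE))
}

# naive all-substring scan: the oracle for exact context matching
naive_match <- function(pattern, target) {
  w <- nchar(pattern)
  n <- nchar(target)
  if (w > n || w == 0) return(integer(0))
  which(vapply(seq_len(n - w + 1), function(i)
    substr(target, i, i + w - 1) == pattern, logical(1)))
}

# enumeration oracle for the one-sided Fisher enrichment tail: sum the
# probabilities of all fixed-margin tables with first cell >= k, each table
# probability computed from binomial coefficients
fisher_oracle <- function(k, n, K, M) {
  s <- k + K                   # column-1 margin
  a_min <- max(0L, s - M)
  a_max <- min(n, s)
  logp <- vapply(seq(a_min, a_max), function(a)
    lchoose(n, a) + lchoose(M, s - a) - lchoose(n + M, s), numeric(1))
  tail <- logp[seq(a_min, a_max) >= k]
  if (length(tail) == 0) return(0)
  mx <- max(tail)
  exp(mx) * sum(exp(tail - mx))
}

# direct step-up definition of the BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q_sorted[i] <- min(pmin(p[ord][js] * m / js, 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# --- path-finding oracle: generate-and-filter enumeration ------------------

# standalone re-statement of the path grammar, applied to an edge sequence
grammar_valid <- function(edge_seq, source, target, implied_p1, window,
                          any_position) {
  L <- nrow(edge_seq)
  if (L == 0) return(FALSE)
  if (edge_seq$from[1] != source) return(FALSE)
  if (edge_seq$type[1] != "cleave") return(FALSE)
  if (L > 1 && any(edge_seq$to[-L] != edge_seq$from[-1])) return(FALSE)
  nodes <- c(edge_seq$from[1], edge_seq$to)
  if (anyDuplicated(nodes) > 0) return(FALSE)
  for (i in seq_len(L - 1))
    if (edge_seq$type[i] == "inhibit" && edge_seq$type[i + 1] != "cleave")
      return(FALSE)
  last <- edge_seq[L, ]
  if (last$type != "cleave" || last$to != target) return(FALSE)
  if (last$origin == "inferred" || any_position || is.na(implied_p1))
    return(TRUE)
  abs(last$position - implied_p1) <= window
}

# enumerate every simple node sequence source -> target (ignoring the
# grammar), expand all parallel-edge choices, then filter with grammar_valid
oracle_find_paths <- function(edges, source, target, implied_p1, max_length,
                              window = 0L, any_position = FALSE) {
  nodes <- unique(c(edges$from, edges$to))
  found <- list()
  expand <- function(node_seq) {
    # all edge choices along the fixed node sequence
    choice_sets <- lapply(seq_len(length(node_seq) - 1), function(i)
      which(edges$from == node_seq[i] & edges$to == node_seq[i + 1]))
    if (any(vapply(choice_sets, length, integer(1)) == 0)) return()
    combos <- do.call(expand.grid, choice_sets)
    for (r in seq_len(nrow(combos))) {
      es <- edges[as.integer(combos[r, ]), , drop = FALSE]
      if (grammar_valid(es, source, target, implied_p1, window, any_position))
        found[[length(found) + 1]] <<- es
    }
  }
  grow <- function(node_seq) {
    if (length(node_seq) - 1 >= max_length) return()
    nxt <- unique(edges$to[edges$from == node_seq[length(node_seq)]])
    for (v in setdiff(nxt, node_seq)) {
      if (v == target) expand(c(node_seq, v))
      grow(c(node_seq, v))
    }
  }
  if (source %in% nodes) grow(source)
  found
}

path_signature <- function(nodes, types, positions) {
  paste(paste(nodes, collapse = ">"), paste(types, collapse = ";"),
        paste(ifelse(is.na(positions), ".", positions), collapse = ";"),
        sep = "|")
}

# signatures of implementation output for one target
impl_signatures <- function(paths_for_target) {
  sort(vapply(paths_for_target, function(p)
    path_signature(p$nodes, p$edge_types, p$positions), character(1)))
}

# signatures of oracle output
oracle_signatures <- function(edge_seq_list) {
  sort(vapply(edge_seq_list, function(es)
    path_signature(c(es$from[1], es$to), es$type, es$position), character(1)))
}

# a random typed web over <= n_nodes nodes with <= n_edges edges
random_web <- function(seed, n_nodes = 8, n_edges = 18) {
  set.seed(seed)
  nn <- sample(4:n_nodes, 1)
  accs <- sprintf("N%02d", seq_len(nn))
  ne <- sample(4:n_edges, 1)
  from <- sample(accs, ne, replace = TRUE)
  to <- sample(accs, ne, replace = TRUE)
  keep <- from != to
  type <- sample(c("cleave", "inhibit"), ne, replace = TRUE,
                 prob = c(0.75, 0.25))
  position <- ifelse(type == "cleave", sample(1:60, ne, replace = TRUE),
                     NA_integer_)
  edges <- data.frame(from = from[keep], to = to[keep], type = type[keep],
                      position = as.integer(position[keep]),
                      origin = "kb", stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$from, edges$to, edges$type,
                                   edges$position)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(accession = sort(unique(c(edges$from, edges$to))),
                      stringsAsFactors = FALSE)
  nodes$is_protease <- nodes$accession %in%
    edges$from[edges$type == "cleave"]
  nodes$is_inhibitor <- nodes$accession %in%
    edges$from[edges$type == "inhibit"]
  structure(list(nodes = nodes, edges = edges), class = "protease_web")
}
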