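# The protease-web path finder: build a typed directed graph of cleavage and
# inhibition events, extend it with hypothesized edges from a candidate
# protease to the observed substrates, and enumerate grammar-valid paths
# explaining each observed cleavage.
#
# Path grammar: a path starts with a cleavage edge out of the query protease;
# a cleavage edge may be followed by another cleavage (the cleaved protease
# acts) or by an inhibition edge (the cleaved inhibitor's inhibition is the
# next link); an inhibition edge must be followed by a cleavage out of the
# inhibited protease; the final edge is a cleavage into the target. Paths are
# node-simple. A path consisting solely of the single inferred query->target
# edge is reported as hypothesized-direct, not as an explanation.

#' Build the protease web from knowledgebase cleavage and inhibition data
#'
#' Nodes are all proteins participating in at least one event; edges are
#' typed: cleavage edges protease -> substrate carrying the P1 position, and
#' inhibition edges inhibitor -> protease. Duplicate edges are collapsed. A
#' node is flagged protease iff it has an outgoing cleavage edge and
#' inhibitor iff it has an outgoing inhibition edge.
#'
#' @param kb a validated \code{termikit_kb}
#' @param species optional species filter: only cleavages of this species
#'   (and inhibitions whose inhibitor belongs to it) are used
#' @return object of class \code{protease_web} with \code{nodes} and
#'   \code{edges} data frames
#' @export
build_web <- function(kb, species = NULL) {
  stopifnot(inherits(kb, "termikit_kb"))
  cl <- kb$cleavages
  ih <- kb$inhibitions
  if (!is.null(species)) {
    cl <- cl[cl$species == species, , drop = FALSE]
    inh_sp <- kb$proteins$species[match(ih$inhibitor_accession,
                                        kb$proteins$accession)]
    ih <- ih[!is.na(inh_sp) & inh_sp == species, , drop = FALSE]
  }
  edges <- rbind(
    data.frame(from = cl$protease_accession, to = cl$substrate_accession,
               type = rep("cleave", nrow(cl)), position = cl$p1_position,
               origin = rep("kb", nrow(cl)), stringsAsFactors = FALSE),
    data.frame(from = ih$inhibitor_accession, to = ih$protease_accession,
               type = rep("inhibit", nrow(ih)),
               position = rep(NA_integer_, nrow(ih)),
               origin = rep("kb", nrow(ih)), stringsAsFactors = FALSE))
  edges <- edges[!duplicated(paste(edges$from, edges$to, edges$type,
                                   edges$position, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$type, edges$position), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  accs <- sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(
    accession = accs,
    is_protease = accs %in% edges$from[edges$type == "cleave"],
    is_inhibitor = accs %in% edges$from[edges$type == "inhibit"],
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "protease_web")
}

#' @export
print.protease_web <- function(x, ...) {
  cat(sprintf("<protease web> %d nodes (%d proteases, %d inhibitors), %d edges (%d cleave, %d inhibit, %d inferred)\n",
              nrow(x$nodes), sum(x$nodes$is_protease),
              sum(x$nodes$is_inhibitor), nrow(x$edges),
              sum(x$edges$type == "cleave"), sum(x$edges$type == "inhibit"),
              sum(x$edges$origin == "inferred")))
  invisible(x)
}

#' Construct a path query
#'
#' @param protease_accession the candidate protease
#' @param targets data frame with columns accession, position (observed
#'   terminus position, NA for position-free matching), terminus_type
#'   ("N"/"C")
#' @param species optional species of the query data
#' @param cross_species map query and targets to the partner species through
#'   the ortholog table before searching
#' @param max_length maximum number of edges per path
#' @param position_window tolerated residue offset between a final cleavage
#'   edge's P1 and the P1 implied by the observed terminus
#' @param any_position accept any knowledgebase cleavage of the target as the
#'   final edge, regardless of position
#' @return object of class \code{path_query}
#' @export
path_query <- function(protease_accession, targets, species = NULL,
                       cross_species = FALSE, max_length = 4L,
                       position_window = 0L, any_position = FALSE) {
  stopifnot(is.character(protease_accession), length(protease_accession) == 1,
            max_length >= 1, position_window >= 0)
  targets <- as.data.frame(targets)
  if (is.null(targets$position)) targets$position <- NA_integer_
  if (is.null(targets$terminus_type)) targets$terminus_type <- "N"
  targets$position <- as.integer(targets$position)
  targets <- targets[, c("accession", "position", "terminus_type")]
  structure(list(protease_accession = protease_accession, targets = targets,
                 species = species, cross_species = cross_species,
                 max_length = as.integer(max_length),
                 position_window = as.integer(position_window),
                 any_position = isTRUE(any_position),
                 positions_approximate = FALSE),
            class = "path_query")
}

implied_p1 <- function(position, terminus_type) {
  ifelse(terminus_type == "N", position - 1L, position)
}

#' Extend a protease web with hypothesized query edges
#'
#' Adds an inferred cleavage edge from the query protease to every target
#' protein at the P1 position implied by its observed terminus. An identical
#' knowledgebase edge is kept with its kb origin; self-edges (target equal to
#' the query protease) and targets whose implied P1 is not a valid position
#' are skipped. The input web is not modified.
#'
#' @param web a \code{protease_web}
#' @param query a \code{path_query}
#' @return a new \code{protease_web} including the inferred edges
#' @export
extend_with_query <- function(web, query) {
  stopifnot(inherits(web, "protease_web"), inherits(query, "path_query"))
  tg <- query$targets
  if (nrow(tg) == 0) return(web)
  p1 <- implied_p1(tg$position, tg$terminus_type)
  new <- data.frame(from = query$protease_accession, to = tg$accession,
                    type = "cleave", position = p1, origin = "inferred",
                    stringsAsFactors = FALSE)
  new <- new[new$to != query$protease_accession &
               (!is.na(new$position) & new$position >= 1), , drop = FALSE]
  kb_key <- with(web$edges, paste(from, to, type, position, sep = "\r"))
  new_key <- with(new, paste(from, to, type, position, sep = "\r"))
  new <- new[!new_key %in% kb_key & !duplicated(new_key), , drop = FALSE]
  out <- web
  out$edges <- rbind(web$edges, new)
  rownames(out$edges) <- NULL
  accs <- sort(unique(c(out$edges$from, out$edges$to)))
  out$nodes <- data.frame(
    accession = accs,
    is_protease = accs %in% out$edges$from[out$edges$type == "cleave" &
                                             out$edges$origin == "kb"],
    is_inhibitor = accs %in% out$edges$from[out$edges$type == "inhibit"],
    stringsAsFactors = FALSE)
  out
}

path_record <- function(edges_df, edge_idx) {
  e <- edges_df[edge_idx, , drop = FALSE]
  list(nodes = c(e$from[1], e$to),
       edge_types = e$type, positions = e$position, origins = e$origin,
       length = nrow(e), is_direct = nrow(e) == 1L,
       contains_inferred = any(e$origin == "inferred"),
       hypothesized_direct = nrow(e) == 1L && e$origin[1] == "inferred")
}

#' Enumerate grammar-valid paths from the query protease to each target
#'
#' Depth-first enumeration of all node-simple paths of at most
#' \code{max_length} edges satisfying the protease-web grammar (see the
#' module header): cleave-only chains and cleave--inhibit--cleave relays; the
#' final edge is a cleavage into the target whose P1 lies within
#' \code{position_window} of the position implied by the observed terminus
#' (inferred final edges match by construction). Per target at most 10000
#' paths are returned, with a truncation flag beyond that.
#'
#' @param web an extended \code{protease_web}
#' @param query a \code{path_query}
#' @param max_paths_per_target hard cap per target; enumeration beyond it is
#'   flagged truncated
#' @return named list (one entry per target accession) of lists of paths;
#'   each path holds nodes, edge_types, positions, origins, length,
#'   is_direct, contains_inferred and hypothesized_direct; truncated targets
#'   are named in the "truncated" attribute
#' @export
find_paths <- function(web, query, max_paths_per_target = 10000L) {
  stopifnot(inherits(web, "protease_web"), inherits(query, "path_query"))
  src <- query$protease_accession
  if (!src %in% web$nodes$accession)
    stop(sprintf("query protease '%s' is not in the protease web", src))
  edges <- web$edges
  out_idx <- split(seq_len(nrow(edges)), edges$from)
  tg <- query$targets
  tg_p1 <- implied_p1(tg$position, tg$terminus_type)
  result <- stats::setNames(vector("list", nrow(tg)), tg$accession)
  for (i in seq_along(result)) result[[i]] <- list()
  truncated <- character(0)

  final_ok <- function(eidx, target_i) {
    e <- edges[eidx, ]
    if (e$type != "cleave" || e$to != tg$accession[target_i]) return(FALSE)
    if (e$origin == "inferred" || query$any_position) return(TRUE)
    if (is.na(tg_p1[target_i])) return(TRUE)
    abs(e$position - tg_p1[target_i]) <= query$position_window
  }

  target_rows <- split(seq_len(nrow(tg)), tg$accession)

  walk <- function(node, visited, prev_type, path_idx) {
    if (length(path_idx) >= query$max_length) return(invisible())
    for (eidx in out_idx[[node]]) {
      e_type <- edges$type[eidx]
      e_to <- edges$to[eidx]
      if (length(path_idx) == 0L && e_type != "cleave") next
      if (identical(prev_type, "inhibit") && e_type != "cleave") next
      if (e_to %in% visited) next
      new_path <- c(path_idx, eidx)
      if (e_type == "cleave" && !is.null(target_rows[[e_to]])) {
        for (ti in target_rows[[e_to]]) {
          if (!final_ok(eidx, ti)) next
          if (length(result[[ti]]) >= max_paths_per_target) {
            truncated <<- union(truncated, tg$accession[ti])
          } else {
            result[[ti]][[length(result[[ti]]) + 1L]] <<-
              path_record(edges, new_path)
          }
        }
      }
      walk(e_to, c(visited, e_to), e_type, new_path)
    }
    invisible()
  }
  walk(src, src, NULL, integer(0))
  # deterministic order: by length, then node sequence
  for (i in seq_along(result)) {
    ps <- result[[i]]
    if (length(ps) > 1) {
      key <- vapply(ps, function(p)
        sprintf("%03d|%s|%s", p$length, paste(p$nodes, collapse = ">"),
                paste(p$positions, collapse = ",")), character(1))
      result[[i]] <- ps[order(key)]
    }
  }
  attr(result, "truncated") <- truncated
  result
}

#' Map a path query to the partner species through the ortholog table
#'
#' The query protease and every target are replaced by their one-to-one
#' ortholog (one-to-many clusters are reduced to the highest-score pair,
#' ties broken by accession). Targets without an ortholog are dropped and
#' reported; observed positions are carried over unchanged and flagged
#' approximate, since residue numbering is species-specific.
#'
#' @param query a \code{path_query} with \code{cross_species = TRUE}
#' @param kb a knowledgebase whose ortholog table is used
#' @return the mapped \code{path_query}; dropped targets are listed in its
#'   "dropped_targets" attribute
#' @export
map_orthologs <- function(query, kb) {
  stopifnot(inherits(query, "path_query"), inherits(kb, "termikit_kb"))
  ot <- kb$orthologs
  both <- rbind(
    data.frame(from = ot$accession_a, to = ot$accession_b,
               to_species = ot$species_b, score = ot$score,
               stringsAsFactors = FALSE),
    data.frame(from = ot$accession_b, to = ot$accession_a,
               to_species = ot$species_a, score = ot$score,
               stringsAsFactors = FALSE))
  # reduce one-to-many: keep the highest score per (from, partner species)
  both <- both[order(both$from, both$to_species, -ifelse(is.na(both$score),
                                                         -Inf, both$score),
                     both$to), , drop = FALSE]
  both <- both[!duplicated(paste(both$from, both$to_species, sep = "\r")), ,
               drop = FALSE]
  lookup <- stats::setNames(both$to, both$from)

  mapped_prot <- lookup[query$protease_accession]
  if (is.na(mapped_prot))
    stop(sprintf("query protease '%s' has no ortholog",
                 query$protease_accession))
  tg <- query$targets
  tg$mapped <- unname(lookup[tg$accession])
  dropped <- tg$accession[is.na(tg$mapped)]
  tg <- tg[!is.na(tg$mapped), , drop = FALSE]
  out <- query
  out$protease_accession <- unname(mapped_prot)
  out$targets <- data.frame(accession = tg$mapped, position = tg$position,
                            terminus_type = tg$terminus_type,
                            stringsAsFactors = FALSE)
  out$positions_approximate <- TRUE
  attr(out, "dropped_targets") <- dropped
  out
}

dot_quote <- function(x) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))

#' Export paths as a Graphviz DOT digraph
#'
#' Emits exactly the union of nodes and edges on the returned paths: the
#' query protease is colored, list proteins are gray-filled; cleavage edges
#' are solid arrows labeled with the P1 position (dotted when inferred from
#' the list); inhibition edges carry tee arrowheads labeled "inh". Node and
#' edge emission is sorted, so the output is deterministic and parseable by
#' standard DOT tools.
#'
#' @param paths result of \code{\link{find_paths}}
#' @param web the extended \code{protease_web} (unused beyond validation;
#'   kept for interface symmetry)
#' @param query_protease accession highlighted as the query node
#' @param list_proteins accessions filled gray (defaults to the path targets)
#' @return DOT source as a single character scalar
#' @export
to_dot <- function(paths, web = NULL, query_protease = NULL,
                   list_proteins = names(paths)) {
  all_paths <- unlist(paths, recursive = FALSE)
  edge_rows <- unique(do.call(rbind, c(list(data.frame(
    from = character(), to = character(), type = character(),
    position = integer(), origin = character(), stringsAsFactors = FALSE)),
    lapply(all_paths, function(p) data.frame(
      from = p$nodes[-length(p$nodes)], to = p$nodes[-1], type = p$edge_types,
      position = p$positions, origin = p$origins,
      stringsAsFactors = FALSE)))))
  edge_rows <- edge_rows[order(edge_rows$from, edge_rows$to, edge_rows$type,
                               edge_rows$position), , drop = FALSE]
  nodes <- sort(unique(c(edge_rows$from, edge_rows$to)))
  lines <- c("digraph protease_web {", "  rankdir=LR;")
  for (nd in nodes) {
    attrs <- character(0)
    if (!is.null(query_protease) && nd == query_protease)
      attrs <- c(attrs, "style=filled", "fillcolor=orange")
    else if (nd %in% list_proteins)
      attrs <- c(attrs, "style=filled", "fillcolor=gray")
    lines <- c(lines, sprintf("  %s%s;", dot_quote(nd),
                              if (length(attrs)) sprintf(" [%s]",
                                paste(attrs, collapse = ", ")) else ""))
  }
  for (i in seq_len(nrow(edge_rows))) {
    e <- edge_rows[i, ]
    attrs <- if (e$type == "inhibit") {
      c("arrowhead=tee", "label=\"inh\"")
    } else {
      c(sprintf("label=\"%d\"", e$position),
        if (e$origin == "inferred") "style=dotted" else "style=solid")
    }
    lines <- c(lines, sprintf("  %s -> %s [%s];", dot_quote(e$from),
                              dot_quote(e$to), paste(attrs, collapse = ", ")))
  }
  paste(c(lines, "}"), collapse = "\n")
}

paths_to_table <- function(paths) {
  rows <- list(data.frame(target = character(), path_rank = integer(),
                          length = integer(), node_sequence = character(),
                          edge_types = character(), positions = character(),
                          contains_inferred = logical(),
                          hypothesized_direct = logical(),
                          stringsAsFactors = FALSE))
  for (tgt in names(paths)) {
    ps <- paths[[tgt]]
    for (r in seq_along(ps)) {
      p <- ps[[r]]
      rows[[length(rows) + 1]] <- data.frame(
        target = tgt, path_rank = r, length = p$length,
        node_sequence = paste(p$nodes, collapse = ">"),
        edge_types = paste(p$edge_types, collapse = ";"),
        positions = paste(ifelse(is.na(p$positions), "", p$positions),
                          collapse = ";"),
        contains_inferred = p$contains_inferred,
        hypothesized_direct = p$hypothesized_direct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the protease-web path-finding analysis for a query list
#'
#' Locates and classifies the query peptides, derives the targets (the
#' cleavage-derived termini, or every located terminus in standalone mode),
#' builds the protease web (optionally mapping query and targets to the
#' partner species through orthologs), extends it with hypothesized edges
#' from the candidate protease and enumerates all grammar-valid paths.
#' Per-target problems are collected as diagnostics; the run never aborts on
#' one bad target.
#'
#' @param query_list data frame as for \code{\link{run_topfinder}}
#' @param protease candidate protease accession
#' @param kb a validated \code{termikit_kb}
#' @param species optional species filter for the web
#' @param cross_species map through the ortholog table
#' @param max_length maximum path length in edges
#' @param window residue window used both for terminus classification and
#'   for final-edge position matching
#' @param any_position accept any knowledgebase cleavage of a target as final
#'   edge
#' @param targets_from "cleaved" restricts targets to cleavage-derived
#'   termini; "located" uses every located terminus
#' @param out_dir optional directory; when given, paths.tsv and paths.dot are
#'   written there
#' @return object of class \code{pathfinder_result}: query, paths, table,
#'   dot, diagnostics
#' @export
run_pathfinder <- function(query_list, protease, kb, species = NULL,
                           cross_species = FALSE, max_length = 4L,
                           window = 0L, any_position = FALSE,
                           targets_from = c("cleaved", "located"),
                           out_dir = NULL) {
  stopifnot(inherits(kb, "termikit_kb"))
  targets_from <- match.arg(targets_from)
  query_list <- as.data.frame(query_list)
  diags <- character(0)
  tg_rows <- list(data.frame(accession = character(), position = integer(),
                             terminus_type = character(),
                             stringsAsFactors = FALSE))
  for (i in seq_len(nrow(query_list))) {
    q <- query_list[i, , drop = FALSE]
    j <- match(q$accession, kb$proteins$accession)
    a <- tryCatch({
      a <- locate_terminus(q, if (is.na(j)) NULL else
        kb$proteins[j, , drop = FALSE])
      classify_terminus(a, kb, window = window)
    }, error = function(e) {
      diags <<- c(diags, sprintf("query %d (%s): %s", i, q$accession,
                                 conditionMessage(e)))
      NULL
    })
    if (is.null(a)) next
    if (a$status != "located") {
      diags <- c(diags, sprintf("query %d (%s): %s", i, q$accession,
                                a$status))
      next
    }
    if (targets_from == "cleaved" && !"cleaved" %in% a$categories) next
    tg_rows[[length(tg_rows) + 1]] <- data.frame(
      accession = q$accession, position = a$position,
      terminus_type = q$terminus_type, stringsAsFactors = FALSE)
  }
  targets <- unique(do.call(rbind, tg_rows))
  query <- path_query(protease, targets, species = species,
                      cross_species = cross_species, max_length = max_length,
                      position_window = window, any_position = any_position)
  if (cross_species) {
    query <- map_orthologs(query, kb)
    dropped <- attr(query, "dropped_targets")
    if (length(dropped) > 0)
      diags <- c(diags, sprintf("target %s: no ortholog, dropped", dropped))
  }
  web <- build_web(kb, species = if (cross_species) NULL else species)
  ext <- extend_with_query(web, query)
  paths <- if (nrow(query$targets) == 0)
    structure(list(), truncated = character(0)) else find_paths(ext, query)
  res <- structure(list(query = query, web = ext, paths = paths,
                        table = paths_to_table(paths),
                        dot = to_dot(paths, ext, query$protease_accession),
                        diagnostics = diags),
                   class = "pathfinder_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(res$table, file.path(out_dir, "paths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    writeLines(res$dot, file.path(out_dir, "paths.dot"))
  }
  res
}

#' @export
print.pathfinder_result <- function(x, ...) {
  n_paths <- sum(vapply(x$paths, length, integer(1)))
  n_expl <- sum(vapply(unlist(x$paths, recursive = FALSE), function(p)
    !p$hypothesized_direct, logical(1)))
  cat(sprintf("<pathfinder result> protease %s, %d target(s)\n",
              x$query$protease_accession, nrow(x$query$targets)))
  cat(sprintf("  %d path(s): %d explanation(s), %d hypothesized-direct\n",
              n_paths, n_expl, n_paths - n_expl))
  if (length(x$diagnostics) > 0)
    cat(sprintf("  %d diagnostic(s)\n", length(x$diagnostics)))
  invisible(x)
}
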