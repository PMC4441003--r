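# Ontology parsing, true-path ancestor expansion, depth and information
# content. The parent relation is the union of is_a and part_of edges; the
# true-path rule (annotation to a term implies annotation to every ancestor)
# is what makes hierarchical evaluation meaningful.

#' Parse an OBO flat file into an ontology graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (id, name, namespace, synonym, is_a,
#' `relationship: part_of`). The parent relation used throughout the package
#' is the union of `is_a` and `part_of`; other relationship types are
#' ignored. Obsolete terms are retained but flagged, and excluded from
#' dictionaries, depth, IC and evaluation.
#'
#' @param path Path to an OBO file.
#' @return A `go_ontology` object: a list with
#'   \describe{
#'     \item{terms}{tibble with `id`, `name`, `namespace`, `obsolete`}
#'     \item{synonyms}{tibble with `id`, `synonym`, `scope`}
#'     \item{edges}{tibble with `id`, `parent`, `relation`}
#'     \item{roots}{named character vector, namespace -> root term id}
#'     \item{ancestors}{named list, term id -> character vector of all
#'       proper ancestors (true-path closure)}
#'   }
#' @details A cycle in the parent relation or a term without a namespace is a
#'   hard error. Each namespace must have exactly one non-obsolete parentless
#'   term (its root).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- str_trim(lines)

  # split into stanzas
  starts <- which(lines == "[Term]")
  other_stanza <- which(grepl("^\\[", lines) & lines != "[Term]")
  terms <- list()
  for (s in seq_along(starts)) {
    from <- starts[s] + 1L
    nxt <- c(starts[starts > starts[s]], other_stanza[other_stanza > starts[s]],
             length(lines) + 1L)
    to <- min(nxt) - 1L
    block <- lines[seq(from, to)]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    fields <- str_match(block, "^([a-z_]+):\\s*(.*)$")
    keys <- fields[, 2]
    vals <- fields[, 3]
    get1 <- function(k) { v <- vals[keys == k]; if (length(v)) v[1] else NA_character_ }
    id <- get1("id")
    if (is.na(id)) next
    name <- get1("name")
    namespace <- get1("namespace")
    obsolete <- identical(get1("is_obsolete"), "true")

    isa <- str_match(vals[keys == "is_a"], "^(\\S+)")[, 2]
    rel <- vals[keys == "relationship"]
    po <- str_match(rel, "^part_of\\s+(\\S+)")[, 2]
    po <- po[!is.na(po)]

    syn_raw <- vals[keys == "synonym"]
    syn <- str_match(syn_raw, '^"(.*)"\\s*([A-Z_]*)')
    terms[[id]] <- list(
      id = id, name = name, namespace = namespace, obsolete = obsolete,
      parents_isa = isa, parents_po = po,
      synonyms = if (length(syn_raw)) {
        tibble(id = id, synonym = syn[, 2],
               scope = ifelse(nzchar(syn[, 3]), syn[, 3], "RELATED"))
      } else NULL
    )
  }
  if (!length(terms)) abort("no [Term] stanzas found in OBO file")

  term_tbl <- tibble(
    id = unname(map_chr(terms, "id")),
    name = unname(map_chr(terms, "name")),
    namespace = unname(map_chr(terms, "namespace")),
    obsolete = map_lgl_(terms, "obsolete")
  )
  if (anyNA(term_tbl$namespace)) {
    abort(paste0("term(s) without namespace: ",
                 paste(term_tbl$id[is.na(term_tbl$namespace)], collapse = ", ")))
  }
  if (anyDuplicated(term_tbl$id)) abort("duplicate term ids in OBO file")

  edges <- bind_rows(
    map(terms, function(t) {
      bind_rows(
        if (length(t$parents_isa)) tibble(id = t$id, parent = t$parents_isa,
                                          relation = "is_a"),
        if (length(t$parents_po)) tibble(id = t$id, parent = t$parents_po,
                                         relation = "part_of")
      )
    })
  )
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(id = character(), parent = character(), relation = character())
  }
  unknown <- setdiff(edges$parent, term_tbl$id)
  if (length(unknown)) {
    abort(paste0("parent id(s) not defined in file: ",
                 paste(unknown, collapse = ", ")))
  }

  synonyms <- bind_rows(compact(map(terms, "synonyms")))
  if (!nrow(synonyms)) {
    synonyms <- tibble(id = character(), synonym = character(), scope = character())
  }

  ont <- new_ontology(term_tbl, edges, synonyms)
  ont
}

map_lgl_ <- function(x, f) vapply(x, function(e) isTRUE(e[[f]]), logical(1),
                                  USE.NAMES = FALSE)

# Assemble and validate a go_ontology from its component tables.
new_ontology <- function(term_tbl, edges, synonyms) {
  live <- term_tbl$id[!term_tbl$obsolete]
  live_edges <- edges[edges$id %in% live & edges$parent %in% live, ]

  order <- topo_order(term_tbl$id, live_edges)  # errors on cycles

  # roots: one non-obsolete parentless term per namespace
  has_parent <- live %in% live_edges$id
  parentless <- live[!has_parent]
  ns_of <- setNames(term_tbl$namespace, term_tbl$id)
  roots <- character()
  for (ns in unique(ns_of[live])) {
    r <- parentless[ns_of[parentless] == ns]
    if (length(r) != 1L) {
      abort(paste0("namespace ", ns, " must have exactly one root, found: ",
                   paste(r, collapse = ", ")))
    }
    roots[ns] <- r
  }

  # true-path ancestor closure (proper ancestors), children before parents
  parent_of <- split(live_edges$parent, live_edges$id)
  anc <- setNames(vector("list", length(live)), live)
  for (id in intersect(order, live)) {  # parents first
    ps <- parent_of[[id]]
    anc[[id]] <- if (is.null(ps)) character() else
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }

  structure(
    list(terms = term_tbl, synonyms = synonyms, edges = edges,
         roots = roots, ancestors = anc),
    class = "go_ontology"
  )
}

# Topological order over parent edges (parents before children among live
# terms). Errors naming a cycle member if the relation is cyclic.
topo_order <- function(ids, edges) {
  n_parents <- table(factor(edges$id, levels = ids))
  remaining <- setNames(as.integer(n_parents), ids)
  children_of <- split(edges$id, edges$parent)
  queue <- ids[remaining == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children_of[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(ids)) {
    stuck <- setdiff(ids, out)
    abort(paste0("cycle detected in ontology parent relation involving ",
                 stuck[1]))
  }
  out
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("<go_ontology> ", nrow(x$terms), " terms (",
      sum(x$terms$obsolete), " obsolete), ", nrow(x$edges), " edges, ",
      length(x$roots), " namespace(s)\n", sep = "")
  invisible(x)
}

#' Proper ancestors of a term
#'
#' All terms reachable from `term` by following `is_a`/`part_of` edges
#' upwards; excludes the term itself.
#'
#' @param ontology A `go_ontology`.
#' @param term A single term id.
#' @return Character vector of ancestor ids (empty for a root).
#' @export
go_ancestors <- function(ontology, term) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (!term %in% names(ontology$ancestors)) {
    abort(paste0("unknown or obsolete term id: ", term))
  }
  ontology$ancestors[[term]]
}

#' Expand a term set under the true-path rule
#'
#' Returns the input terms plus all their ancestors. The result is closed
#' under the parent relation and the operation is idempotent; it is applied
#' to both gold annotations and predictions before any comparison.
#'
#' @param ontology A `go_ontology`.
#' @param terms Character vector of term ids.
#' @return Character vector: `terms` union all ancestors (unique, unordered).
#' @export
expand_true_path <- function(ontology, terms) {
  stopifnot(inherits(ontology, "go_ontology"))
  terms <- unique(terms)
  bad <- setdiff(terms, names(ontology$ancestors))
  if (length(bad)) {
    abort(paste0("unknown or obsolete term id(s): ", paste(bad, collapse = ", ")))
  }
  unique(c(terms, unlist(ontology$ancestors[terms], use.names = FALSE)))
}

#' Shortest-path depth of every term
#'
#' Depth is the length of the shortest path from the namespace root to the
#' term following parent edges downward; the root has depth 0 and its direct
#' children depth 1. Obsolete terms are excluded.
#'
#' @param ontology A `go_ontology`.
#' @return A tibble with columns `id`, `namespace`, `depth`.
#' @export
term_depths <- function(ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  live <- ontology$terms$id[!ontology$terms$obsolete]
  edges <- ontology$edges[ontology$edges$id %in% live &
                          ontology$edges$parent %in% live, ]
  children_of <- split(edges$id, edges$parent)
  depth <- setNames(rep(NA_integer_, length(live)), live)
  for (root in ontology$roots) {
    depth[root] <- 0L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (ch in children_of[[v]]) {
        if (is.na(depth[ch]) || depth[ch] > depth[v] + 1L) {
          depth[ch] <- depth[v] + 1L
          queue <- c(queue, ch)
        }
      }
    }
  }
  if (anyNA(depth)) {
    abort(paste0("term(s) unreachable from their namespace root: ",
                 paste(names(depth)[is.na(depth)], collapse = ", ")))
  }
  ns_of <- setNames(ontology$terms$namespace, ontology$terms$id)
  tibble(id = names(depth), namespace = unname(ns_of[names(depth)]),
         depth = unname(depth)) |>
    arrange(.data$namespace, .data$depth, .data$id)
}

#' Annotation-based information content (Resnik)
#'
#' For each term t, p(t) is the fraction of proteins whose true-path-expanded
#' gold annotation set contains t, among proteins with at least one
#' annotation in t's namespace; ic(t) = -log p(t). The root always has
#' ic = 0 and ic is monotone non-decreasing from root to leaves. Terms never
#' seen in the expanded gold set (p = 0) are omitted.
#'
#' @param ontology A `go_ontology`.
#' @param gold A tibble of gold annotations with columns `protein`, `go_id`
#'   (as returned by [read_gaf()]).
#' @param base Log base; default `exp(1)` gives nats, use 2 for bits.
#' @return A tibble with columns `id`, `namespace`, `ic`.
#' @export
term_ic <- function(ontology, gold, base = exp(1)) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (is.null(gold) || !nrow(gold)) abort("gold annotation set is empty")
  ns_of <- setNames(ontology$terms$namespace, ontology$terms$id)
  gold <- gold |>
    distinct(.data$protein, .data$go_id) |>
    mutate(namespace = unname(ns_of[.data$go_id]))
  if (anyNA(gold$namespace)) {
    abort("gold annotations reference term ids absent from the ontology")
  }
  out <- list()
  for (ns in unique(gold$namespace)) {
    g <- gold[gold$namespace == ns, ]
    n_prot <- n_distinct(g$protein)
    expanded <- g |>
      group_by(.data$protein) |>
      reframe(go_id = expand_true_path(ontology, .data$go_id))
    counts <- expanded |> count(.data$go_id, name = "n_annotated")
    out[[ns]] <- tibble(
      id = counts$go_id, namespace = ns,
      ic = -log(counts$n_annotated / n_prot) / log(base)
    )
  }
  bind_rows(out) |> arrange(.data$namespace, .data$ic, .data$id)
}

#' Serialize an ontology graph to an OBO flat file
#'
#' Writes `[Term]` stanzas with id, name, namespace, synonyms, `is_a` and
#' `relationship: part_of` lines; `read_obo()` of the output reproduces the
#' graph.
#'
#' @param ontology A `go_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "go_ontology"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    out <- c("[Term]",
             paste0("id: ", t$id),
             paste0("name: ", t$name),
             paste0("namespace: ", t$namespace))
    syn <- ontology$synonyms[ontology$synonyms$id == t$id, ]
    if (nrow(syn)) {
      out <- c(out, paste0("synonym: \"", syn$synonym, "\" ", syn$scope, " []"))
    }
    ed <- ontology$edges[ontology$edges$id == t$id, ]
    if (nrow(ed)) {
      isa <- ed$parent[ed$relation == "is_a"]
      po <- ed$parent[ed$relation == "part_of"]
      out <- c(out,
               if (length(isa)) paste0("is_a: ", isa),
               if (length(po)) paste0("relationship: part_of ", po))
    }
    if (t$obsolete) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
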