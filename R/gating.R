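#' Path to the default gating configuration shipped with the package
#'
#' @return File path of `gating_default.yaml`, the default exclusive gating
#'   hierarchy with 23 terminal cell lineages/states (18 T cell states).
#' @export
gating_default_path <- function() {
  system.file("extdata", "gating_default.yaml", package = "spatialTME",
              mustWork = TRUE)
}

#' Load and validate a gating configuration
#'
#' Parses a YAML gating hierarchy into a validated `gating_config` object.
#' A gate node matches a cell when all `require_positive` markers are
#' positive, all `require_negative` markers are negative and, when a
#' `require_any` set is present, at least one of its markers is positive.
#' Siblings are evaluated in listed order and the first match wins, so the
#' hierarchy partitions cells into exclusive populations.
#'
#' @param path YAML file; defaults to the shipped hierarchy.
#' @return A `gating_config`: panel markers, node table, ordered children
#'   map, and the leaf taxonomy (with T-state and T_REG flags).
#' @export
load_gating_config <- function(path = gating_default_path()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$nodes) || is.null(raw$panel)) {
    stop("gating config must contain 'panel' and 'nodes'")
  }
  panel <- as.character(raw$panel)

  nodes <- lapply(raw$nodes, function(nd) {
    list(
      name = as.character(nd$name),
      parent = if (is.null(nd$parent)) NA_character_ else as.character(nd$parent),
      pos = as.character(nd$require_positive %||% character()),
      neg = as.character(nd$require_negative %||% character()),
      any = as.character(nd$require_any %||% character()),
      terminal = isTRUE(nd$terminal),
      t_state = isTRUE(nd$t_state),
      treg = isTRUE(nd$treg)
    )
  })
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(names(nodes))) {
    stop("duplicate node name: ", names(nodes)[duplicated(names(nodes))][1])
  }

  roots <- names(nodes)[vapply(nodes, function(n) is.na(n$parent), TRUE)]
  if (length(roots) != 1L) stop("gating config must have exactly one root")

  for (nd in nodes) {
    bad <- setdiff(c(nd$pos, nd$neg, nd$any), panel)
    if (length(bad)) {
      stop("gate '", nd$name, "' references marker(s) not in the panel: ",
           paste(bad, collapse = ", "))
    }
    if (!is.na(nd$parent) && !nd$parent %in% names(nodes)) {
      stop("gate '", nd$name, "' has unknown parent '", nd$parent, "'")
    }
  }

  # cycle detection by walking each node up to the root
  for (nm in names(nodes)) {
    seen <- character()
    cur <- nm
    while (!is.na(nodes[[cur]]$parent)) {
      if (cur %in% seen) stop("cyclic parent links at node '", cur, "'")
      seen <- c(seen, cur)
      cur <- nodes[[cur]]$parent
      if (cur == nm) stop("cyclic parent links at node '", nm, "'")
    }
  }

  children <- lapply(names(nodes), function(nm) {
    names(nodes)[vapply(nodes, function(n) identical(n$parent, nm), TRUE)]
  })
  names(children) <- names(nodes)

  # identical sibling predicates would make the later one unreachable
  for (nm in names(children)) {
    sibs <- children[[nm]]
    if (length(sibs) < 2L) next
    sig <- vapply(sibs, function(s) {
      nd <- nodes[[s]]
      paste(paste(sort(nd$pos), collapse = ","),
            paste(sort(nd$neg), collapse = ","),
            paste(sort(nd$any), collapse = ","), sep = "|")
    }, "")
    if (anyDuplicated(sig)) {
      dup <- sibs[duplicated(sig)][1]
      stop("siblings with identical predicates under '", nm, "' (e.g. '",
           dup, "')")
    }
  }

  leaves <- names(nodes)[vapply(nodes, `[[`, TRUE, "terminal")]
  taxonomy <- data.frame(
    leaf = leaves,
    t_state = vapply(nodes[leaves], `[[`, TRUE, "t_state"),
    treg = vapply(nodes[leaves], `[[`, TRUE, "treg"),
    stringsAsFactors = FALSE
  )

  structure(
    list(panel = panel, nodes = nodes, children = children, root = roots,
         taxonomy = taxonomy),
    class = "gating_config"
  )
}

#' @export
print.gating_config <- function(x, ...) {
  cat("Gating configuration:", length(x$nodes), "gates,",
      nrow(x$taxonomy), "terminal states (",
      sum(x$taxonomy$t_state), "T states,",
      sum(x$taxonomy$treg), "T_REG states )\n")
  invisible(x)
}

#' Ordered taxonomy leaves of a gating configuration
#'
#' @param config A `gating_config`.
#' @param t_states_only Return only T-state leaves.
#' @return Character vector of leaf labels in document order (stable).
#' @export
taxonomy_leaves <- function(config, t_states_only = FALSE) {
  tx <- config$taxonomy
  if (t_states_only) tx$leaf[tx$t_state] else tx$leaf
}

#' T_REG state labels of a configuration
#' @param config A `gating_config`.
#' @export
treg_leaves <- function(config) {
  config$taxonomy$leaf[config$taxonomy$treg]
}

# evaluate one gate's predicate on a logical marker matrix restricted to idx
.gate_matches <- function(nd, M, idx) {
  ok <- rep(TRUE, length(idx))
  for (m in nd$pos) ok <- ok & M[idx, m]
  for (m in nd$neg) ok <- ok & !M[idx, m]
  if (length(nd$any)) {
    hit <- rep(FALSE, length(idx))
    for (m in nd$any) hit <- hit | M[idx, m]
    ok <- ok & hit
  }
  ok
}

#' Assign every cell exactly one taxonomy leaf
#'
#' Walks the exclusive gating hierarchy for every cell: at each level the
#' first sibling whose predicate matches claims the cell; terminal gates
#' assign the state. Cells matched by no terminal gate fall into the
#' residual "Other" class.
#'
#' @param cells Cell table (data frame) with one logical/0-1 column per
#'   panel marker referenced by the configuration.
#' @param config A `gating_config`.
#' @return `cells` with a `state` column added (or overwritten).
#' @export
assign_states <- function(cells, config) {
  used <- unique(unlist(lapply(config$nodes, function(n) c(n$pos, n$neg, n$any))))
  for (m in used) {
    if (!m %in% names(cells)) {
      gate <- names(config$nodes)[vapply(
        config$nodes, function(n) m %in% c(n$pos, n$neg, n$any), TRUE)][1]
      stop("marker '", m, "' required by gate '", gate,
           "' is missing from the cell table")
    }
  }
  M <- vapply(used, function(m) as.logical(cells[[m]]), logical(nrow(cells)))
  if (nrow(cells) == 1L) M <- matrix(M, nrow = 1, dimnames = list(NULL, used))

  state <- rep(NA_character_, nrow(cells))
  recurse <- function(node, idx) {
    for (child in config$children[[node]]) {
      if (!length(idx)) break
      hit <- .gate_matches(config$nodes[[child]], M, idx)
      got <- idx[hit]
      if (length(got)) {
        if (config$nodes[[child]]$terminal) {
          state[got] <<- child
        } else {
          recurse(child, got)
        }
      }
      idx <- idx[!hit]
    }
  }
  recurse(config$root, seq_len(nrow(cells)))

  if (anyNA(state)) {
    if ("Other" %in% config$taxonomy$leaf) {
      state[is.na(state)] <- "Other"
    } else {
      stop(sum(is.na(state)),
           " cell(s) match no terminal gate and the taxonomy has no 'Other' leaf")
    }
  }
  cells$state <- state
  cells
}

#' Marker constraints that deterministically gate a cell into one leaf
#'
#' For a terminal state, derives the minimal forced-positive / forced-negative
#' marker sets such that any cell satisfying them -- with all remaining panel
#' markers free -- is assigned exactly that leaf under first-match-wins
#' gating. Used by the synthetic generator so planted states are recovered
#' exactly by [assign_states()].
#'
#' The derivation fixes every predicate on the root-to-leaf path, then
#' satisfies two kinds of obligations by a backtracking search over single
#' marker forcings: each path node's any-clause must hold, and every
#' earlier sibling of each path node must be contradicted (made
#' unsatisfiable whatever the free markers do), which is exactly what
#' first-match-wins exclusivity requires.
#'
#' @param config A `gating_config`.
#' @param leaf A terminal state label.
#' @return List with character vectors `pos`, `neg`, and `free`.
#' @export
derive_state_constraints <- function(config, leaf) {
  if (!leaf %in% config$taxonomy$leaf) stop("'", leaf, "' is not a taxonomy leaf")
  nodes <- config$nodes

  # path root -> leaf (excluding root)
  path <- character()
  cur <- leaf
  while (!is.na(nodes[[cur]]$parent)) {
    path <- c(cur, path)
    cur <- nodes[[cur]]$parent
  }

  pos <- character(); neg <- character()
  for (nm in path) {
    pos <- union(pos, nodes[[nm]]$pos)
    neg <- union(neg, nodes[[nm]]$neg)
  }
  if (length(intersect(pos, neg))) {
    stop("gating config for '", leaf, "' is not generable: conflicting ",
         "constraints on ", paste(intersect(pos, neg), collapse = ", "))
  }

  obligations <- list()
  for (nm in path) {
    nd <- nodes[[nm]]
    if (length(nd$any)) {
      obligations[[length(obligations) + 1L]] <-
        list(type = "any", markers = nd$any)
    }
    sibs <- config$children[[nd$parent]]
    for (s in sibs[seq_len(match(nm, sibs) - 1L)]) {
      obligations[[length(obligations) + 1L]] <-
        list(type = "contradict", sib = s)
    }
  }

  contradicted <- function(nd, pos, neg) {
    any(nd$pos %in% neg) || any(nd$neg %in% pos) ||
      (length(nd$any) > 0 && all(nd$any %in% neg))
  }
  solve <- function(pos, neg, obs) {
    if (!length(obs)) return(list(pos = pos, neg = neg))
    ob <- obs[[1]]; rest <- obs[-1]
    if (ob$type == "any") {
      if (any(ob$markers %in% pos)) return(solve(pos, neg, rest))
      for (m in setdiff(ob$markers, neg)) {
        r <- solve(union(pos, m), neg, rest)
        if (!is.null(r)) return(r)
      }
      return(NULL)
    }
    sd <- nodes[[ob$sib]]
    if (contradicted(sd, pos, neg)) return(solve(pos, neg, rest))
    for (m in setdiff(sd$pos, pos)) {       # force one required-positive off
      r <- solve(pos, union(neg, m), rest)
      if (!is.null(r)) return(r)
    }
    for (m in setdiff(setdiff(sd$neg, neg), pos)) {  # force one required-negative on
      r <- solve(union(pos, m), neg, rest)
      if (!is.null(r)) return(r)
    }
    if (length(sd$any) && !any(sd$any %in% pos)) {   # kill the whole any-clause
      r <- solve(pos, union(neg, sd$any), rest)
      if (!is.null(r)) return(r)
    }
    NULL
  }
  sol <- solve(pos, neg, obligations)
  if (is.null(sol)) {
    stop("gating config for '", leaf, "' is not generable: no marker ",
         "assignment avoids all earlier siblings")
  }
  list(pos = sol$pos, neg = sol$neg,
       free = setdiff(config$panel, c(sol$pos, sol$neg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
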