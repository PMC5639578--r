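# Minimal-cost gain/loss histories of intron-site states on a rooted tree.
#
# States: S (stwintron), I (standard intron), N (no intronic sequence).
# The default cost model is Dollo-style: regain after complete loss is
# forbidden (N -> S and N -> I cost Inf), while stwintronisation (I -> S,
# the gain of an internal intron inside a pre-extant intron), internal-intron
# loss (S -> I), full stwintron loss (S -> N) and standard intron loss
# (I -> N) each cost 1.

site_states <- c("S", "I", "N")

#' Transition cost model for site states
#'
#' @param costs optional 3x3 numeric matrix with dimnames `S`, `I`, `N`
#'   (rows = parent state, columns = child state). Defaults described above.
#'   Diagonal entries must be 0; all costs non-negative or `Inf`.
#' @param strict_dollo if `TRUE`, additionally forbids `I -> S` gains —
#'   useful once the single gain branch of a history has been fixed.
#' @return object of class `cost_model` (the validated matrix).
#' @export
cost_model <- function(costs = NULL, strict_dollo = FALSE) {
  if (is.null(costs)) {
    costs <- matrix(c(0, 1, 1,
                      1, 0, 1,
                      Inf, Inf, 0),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(site_states, site_states))
  }
  costs <- as.matrix(costs)
  if (!identical(dim(costs), c(3L, 3L)) ||
      !identical(rownames(costs), site_states) ||
      !identical(colnames(costs), site_states))
    stop("costs must be a 3x3 matrix with dimnames S, I, N")
  if (any(diag(costs) != 0)) stop("identity transitions must cost 0")
  if (any(costs < 0)) stop("costs must be non-negative or Inf")
  if (strict_dollo) costs["I", "S"] <- Inf
  structure(costs, class = c("cost_model", "matrix"))
}

event_kind <- function(from, to) {
  ifelse(from == "S" & to == "I", "internal_loss",
  ifelse(from == "S" & to == "N", "full_loss",
  ifelse(from == "I" & to == "N", "intron_loss",
  ifelse(to == "S" & from == "I", "gain", "other"))))
}

# Normalise tip states; prune NO_GENE tips.
prep_tree_states <- function(tree, tip_states) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. with ape::root) before inference")
  tip_states <- toupper(unlist(tip_states))
  unknown <- setdiff(names(tip_states), tree$tip.label)
  if (length(unknown))
    stop("unknown leaf in tip_states: ", paste(unknown, collapse = ", "))
  ng <- names(tip_states)[tip_states %in% c("NG", "NO_GENE")]
  if (length(ng)) {
    if (length(setdiff(tree$tip.label, ng)) < 2)
      stop("fewer than two leaves remain after pruning NO_GENE tips")
    tree <- ape::drop.tip(tree, ng)
    tip_states <- tip_states[!names(tip_states) %in% ng]
  }
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stop("no state for leaf: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(tip_states), site_states)
  if (length(bad)) stop("invalid tip state(s): ", paste(bad, collapse = ", "))
  list(tree = tree, tip_states = tip_states[tree$tip.label])
}

#' Sankoff minimal-cost ancestral state inference
#'
#' Exact minimum total transition cost by bottom-up dynamic programming over
#' the three site states, with an exact count of co-optimal labelings.
#' Ties between co-optimal labelings are reported via `n_optimal`, never
#' silently broken; the single labeling returned resolves ties
#' deterministically in state order S, I, N.
#'
#' @param tree rooted `phylo` tree with unique tip labels.
#' @param tip_states named character vector of leaf states in
#'   `{S, I, N, NG}`; `NG`/`NO_GENE` leaves are pruned before inference.
#' @param cost [cost_model()].
#' @param root_state optional fixed root state; by default the minimum over
#'   root states is unconstrained.
#' @return object of class `event_labeling`: list with `states` (named vector
#'   over all nodes), `events` (`data.frame`: `branch_child`, `from`, `to`,
#'   `kind`), `total_cost`, `n_optimal`, `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((Pcap,Pcit),(X,Y));")
#' sankoff(tr, c(Pcap = "N", Pcit = "I", X = "S", Y = "S"))$total_cost
#' @export
sankoff <- function(tree, tip_states, cost = cost_model(), root_state = NULL) {
  pp <- prep_tree_states(tree, tip_states)
  tree <- pp$tree; tip_states <- pp$tip_states
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  C <- matrix(Inf, nrow = ntip + nnode, ncol = 3,
              dimnames = list(NULL, site_states))
  CNT <- matrix(0, nrow = ntip + nnode, ncol = 3,
                dimnames = list(NULL, site_states))
  for (i in seq_len(ntip)) {
    C[i, tip_states[tree$tip.label[i]]] <- 0
    CNT[i, tip_states[tree$tip.label[i]]] <- 1
  }
  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  # postorder over internal nodes
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (v in po) {
    kids <- children[[as.character(v)]]
    for (s in 1:3) {
      tot <- 0; cnt <- 1
      for (k in kids) {
        vals <- cost[s, ] + C[k, ]
        m <- min(vals)
        tot <- tot + m
        cnt <- cnt * if (is.finite(m)) sum(CNT[k, vals == m]) else 0
      }
      C[v, s] <- tot
      CNT[v, s] <- cnt
    }
  }
  root_allowed <- if (is.null(root_state)) site_states else {
    if (!root_state %in% site_states) stop("invalid root_state")
    root_state
  }
  rc <- C[root, root_allowed]
  total <- min(rc)
  if (!is.finite(total))
    stop("no feasible labeling: the cost model forbids every history ",
         "consistent with these tip states (a forbidden regain is required)")
  opt_roots <- root_allowed[rc == total]
  n_optimal <- sum(CNT[root, opt_roots])
  # backtrack one optimal labeling (ties resolved in state order S, I, N)
  states <- character(ntip + nnode)
  states[seq_len(ntip)] <- tip_states[tree$tip.label]
  states[root] <- opt_roots[1]
  ed <- ape::reorder.phylo(tree, "cladewise")$edge   # parent before child
  for (r in seq_len(nrow(ed))) {
    par <- ed[r, 1]; ch <- ed[r, 2]
    if (ch <= ntip) next
    vals <- cost[states[par], ] + C[ch, ]
    states[ch] <- site_states[which.min(vals)]
  }
  node_labels <- c(tree$tip.label,
                   if (!is.null(tree$node.label) &&
                       length(tree$node.label) == nnode &&
                       all(nzchar(tree$node.label))) tree$node.label
                   else paste0("node", seq_len(nnode) + ntip))
  names(states) <- node_labels
  ev <- do.call(rbind, lapply(seq_len(nrow(edge)), function(r) {
    from <- states[edge[r, 1]]; to <- states[edge[r, 2]]
    if (from == to) return(NULL)
    data.frame(branch_child = node_labels[edge[r, 2]], from = from, to = to,
               kind = event_kind(from, to), stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(branch_child = character(0), from = character(0),
                     to = character(0), kind = character(0))
  rownames(ev) <- NULL
  structure(list(states = states, events = ev, total_cost = unname(total),
                 n_optimal = unname(n_optimal), tree = tree),
            class = "event_labeling")
}

#' @export
print.event_labeling <- function(x, ...) {
  cat(sprintf("<event_labeling> total cost %g; %d event(s); %d co-optimal labeling(s)\n",
              x$total_cost, nrow(x$events), x$n_optimal))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Count independent loss events in a minimal-cost history
#'
#' Number of branches carrying the requested transition kind in a minimum-cost
#' labeling: `full` counts complete loss of intronic sequence (S->N, I->N),
#' `internal` counts internal-intron-only loss (S->I), `any` counts both.
#' When co-optimal labelings disagree, the minimum over labelings is returned
#' together with an ambiguity flag (and the maximum).
#'
#' @inheritParams sankoff
#' @param loss_kind one of `"any"`, `"full"`, `"internal"`.
#' @return list with `count` (minimum over co-optimal labelings),
#'   `ambiguous`, `max_count`, `total_cost`.
#' @export
count_independent_losses <- function(tree, tip_states,
                                     loss_kind = c("any", "full", "internal"),
                                     cost = cost_model(), root_state = NULL) {
  loss_kind <- match.arg(loss_kind)
  pp <- prep_tree_states(tree, tip_states)
  tree <- pp$tree; tip_states <- pp$tip_states
  is_loss <- matrix(FALSE, 3, 3, dimnames = list(site_states, site_states))
  if (loss_kind %in% c("any", "full")) {
    is_loss["S", "N"] <- TRUE; is_loss["I", "N"] <- TRUE
  }
  if (loss_kind %in% c("any", "internal")) is_loss["S", "I"] <- TRUE
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  C <- matrix(Inf, nrow = ntip + tree$Nnode, ncol = 3)
  LO <- matrix(Inf, nrow = ntip + tree$Nnode, ncol = 3)  # min losses | optimal
  HI <- matrix(-Inf, nrow = ntip + tree$Nnode, ncol = 3) # max losses | optimal
  for (i in seq_len(ntip)) {
    s <- match(tip_states[tree$tip.label[i]], site_states)
    C[i, s] <- 0; LO[i, s] <- 0; HI[i, s] <- 0
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (v in po) {
    kids <- children[[as.character(v)]]
    for (s in 1:3) {
      tot <- 0; lo <- 0; hi <- 0
      for (k in kids) {
        vals <- cost[s, ] + C[k, ]
        m <- min(vals)
        tot <- tot + m
        if (is.finite(m)) {
          opt <- which(vals == m)
          lo <- lo + min(is_loss[s, opt] + LO[k, opt])
          hi <- hi + max(is_loss[s, opt] + HI[k, opt])
        }
      }
      C[v, s] <- tot
      if (is.finite(tot)) { LO[v, s] <- lo; HI[v, s] <- hi }
    }
  }
  root_allowed <- if (is.null(root_state)) 1:3 else
    match(match.arg(root_state, site_states), site_states)
  total <- min(C[root, root_allowed])
  if (!is.finite(total)) stop("no feasible labeling under this cost model")
  opt <- root_allowed[C[root, root_allowed] == total]
  lo <- min(LO[root, opt]); hi <- max(HI[root, opt])
  list(count = as.integer(lo), ambiguous = lo != hi,
       max_count = as.integer(hi), total_cost = unname(total))
}

#' Write the event report as TSV
#'
#' One row per non-identity branch: child label, from-state, to-state, kind.
#' @param labeling `event_labeling` from [sankoff()].
#' @param path output path.
#' @export
write_event_tsv <- function(labeling, path) {
  utils::write.table(labeling$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Annotated Newick output with node-state comments
#'
#' Node states are appended to labels as `label_STATE`.
#' @param labeling `event_labeling`.
#' @param path output path.
#' @export
write_annotated_newick <- function(labeling, path) {
  tr <- labeling$tree
  ntip <- length(tr$tip.label)
  st <- labeling$states
  tr$tip.label <- paste0(tr$tip.label, "_", st[seq_len(ntip)])
  tr$node.label <- paste0(names(st)[(ntip + 1):length(st)], "_",
                          st[(ntip + 1):length(st)])
  ape::write.tree(tr, file = path)
  invisible(path)
}
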