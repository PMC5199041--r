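# Binary-trait gain/loss reconstruction by equal-cost Sankoff parsimony, and
# interface-residue conservation summaries.
#
# Traits here are "represses the Spo0A pathway" / "represses the ComA
# pathway": binary states scored at the tips of a receptor tree. The Sankoff
# dynamic program with unit gain/loss costs returns a minimum-event
# assignment of ancestral states; the root can be fixed (e.g. Spo0A-control
# on, reflecting the ancestral receptor activity) or left free. Ambiguities
# in the minimal assignment are resolved by preferring the parent's state
# (delayed transformation); accelerated transformation is selectable.

#' Binarize target-regulation measurements
#'
#' Converts sporulation-efficiency and reporter-expression measurements into
#' binary repression traits. Repression drives the measurement *down*, so a
#' trait is scored 1 when the measurement is strictly below its cutoff;
#' values at the cutoff are scored 0 ("not repressing"). Missing
#' measurements yield `NA`, which later enters the parsimony as an
#' unconstrained tip.
#'
#' @param measurements data.frame with columns `taxon`,
#'   `sporulation_efficiency`, `reporter_expression`.
#' @param thresholds List with `sporulation_cutoff` and `reporter_cutoff`
#'   (both positive).
#' @return data.frame: `taxon`, `represses_spo0a`, `represses_coma`
#'   (0/1/`NA`).
#' @export
binarize_targets <- function(measurements, thresholds) {
  stopifnot(all(c("taxon", "sporulation_efficiency", "reporter_expression")
                %in% names(measurements)),
            thresholds$sporulation_cutoff > 0, thresholds$reporter_cutoff > 0)
  below <- function(x, cut) ifelse(is.na(x), NA_integer_,
                                   as.integer(x < cut))
  data.frame(taxon = measurements$taxon,
             represses_spo0a = below(measurements$sporulation_efficiency,
                                     thresholds$sporulation_cutoff),
             represses_coma = below(measurements$reporter_expression,
                                    thresholds$reporter_cutoff),
             stringsAsFactors = FALSE)
}

#' Gain/loss parsimony for a binary trait
#'
#' Sankoff dynamic program with unit gain and loss costs. The minimal total
#' event count is exact; one minimal assignment of ancestral states is
#' reported, with ties resolved by preferring the parent's state
#' (`resolve = "deltran"`, default) or the opposite (`"acctran"`). With
#' `root_state` fixed, minimisation is over assignments consistent with that
#' root. Tips with `NA` state are unconstrained. Every run is verified to be
#' locally optimal (no single internal-state flip reduces the event count).
#'
#' @param tree A rooted binary [ape::phylo] tree covering all taxa.
#' @param states Named vector of tip states (0/1/`NA`), names matching tip
#'   labels.
#' @param root_state `NULL` (free) or 0/1.
#' @param resolve Ambiguity rule, `"deltran"` or `"acctran"`.
#' @return List of class `gainloss_result`: `n_events`, `events` (data.frame
#'   `parent`, `child`, `type` = gain/loss, `child_label`), `node_states`
#'   (states for all tips+nodes), `root_state`, `ambiguous_nodes`.
#' @export
parsimony_gainloss <- function(tree, states, root_state = NULL,
                               resolve = c("deltran", "acctran")) {
  resolve <- match.arg(resolve)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing)) stop("tips without states: ",
                            paste(utils::head(missing, 5), collapse = ", "),
                            call. = FALSE)
  extra <- setdiff(names(states), tips)
  if (length(extra)) stop("state taxa absent from tree: ",
                          paste(utils::head(extra, 5), collapse = ", "),
                          call. = FALSE)
  s_tip <- as.integer(states[tips])
  n_tip <- length(tips); n_node <- tree$Nnode
  n_all <- n_tip + n_node
  INF <- .Machine$double.xmax / 4
  cost <- matrix(0, n_all, 2L)  # columns: state 0, state 1
  for (i in seq_len(n_tip)) {
    if (!is.na(s_tip[i])) {
      cost[i, ] <- INF
      cost[i, s_tip[i] + 1L] <- 0
    }
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(post[, 2L], post[, 1L])
  # postorder over internal nodes: parents appear after their children
  internal_order <- unique(post[, 1L])
  for (p in internal_order) {
    for (ch in children[[as.character(p)]]) {
      add0 <- min(cost[ch, 1L], cost[ch, 2L] + 1)
      add1 <- min(cost[ch, 1L] + 1, cost[ch, 2L])
      cost[p, 1L] <- cost[p, 1L] + add0
      cost[p, 2L] <- cost[p, 2L] + add1
    }
  }
  root <- n_tip + 1L
  if (is.null(root_state)) {
    root_assigned <- which.min(cost[root, ]) - 1L  # tie -> state 0
  } else {
    stopifnot(root_state %in% c(0L, 1L))
    root_assigned <- as.integer(root_state)
  }
  n_events <- cost[root, root_assigned + 1L]
  if (n_events >= INF) stop("tip states incompatible with fixed root",
                            call. = FALSE)
  # top-down backtrack
  node_states <- rep(NA_integer_, n_all)
  ambiguous <- logical(n_all)
  node_states[root] <- root_assigned
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]  # preorder edges
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    sp <- node_states[p]
    v0 <- cost[ch, 1L] + (sp != 0L)
    v1 <- cost[ch, 2L] + (sp != 1L)
    if (v0 == v1) {
      ambiguous[ch] <- TRUE
      node_states[ch] <- if (resolve == "deltran") sp else 1L - sp
    } else {
      node_states[ch] <- if (v0 < v1) 0L else 1L
    }
  }
  changed <- node_states[tree$edge[, 1L]] != node_states[tree$edge[, 2L]]
  ev_ix <- which(changed)
  events <- data.frame(
    parent = tree$edge[ev_ix, 1L], child = tree$edge[ev_ix, 2L],
    type = ifelse(node_states[tree$edge[ev_ix, 2L]] == 1L, "gain", "loss"),
    child_label = ifelse(tree$edge[ev_ix, 2L] <= n_tip,
                         tips[tree$edge[ev_ix, 2L]], NA_character_),
    stringsAsFactors = FALSE)
  stopifnot(nrow(events) == n_events)  # DP optimum equals realised changes
  # local-optimality audit: flipping any single internal (non-fixed-root)
  # state must not reduce the number of state changes along edges
  edge_changes <- function(ns) sum(ns[tree$edge[, 1L]] != ns[tree$edge[, 2L]])
  base <- edge_changes(node_states)
  for (v in (n_tip + 1L):n_all) {
    if (v == root && !is.null(root_state)) next
    alt <- node_states; alt[v] <- 1L - alt[v]
    if (edge_changes(alt) < base) {
      stop("internal error: assignment not locally optimal", call. = FALSE)
    }
  }
  structure(list(n_events = as.integer(n_events), events = events,
                 node_states = node_states, root_state = root_assigned,
                 ambiguous_nodes = which(ambiguous)),
            class = "gainloss_result")
}

#' @export
print.gainloss_result <- function(x, ...) {
  cat("<gainloss_result>", x$n_events, "event(s);",
      sum(x$events$type == "gain"), "gain(s),",
      sum(x$events$type == "loss"), "loss(es); root state", x$root_state, "\n")
  invisible(x)
}

#' Number of independent gains of a trait
#'
#' @param result A `gainloss_result`.
#' @return Count of branches labelled gain.
#' @export
count_independent_gains <- function(result) {
  sum(result$events$type == "gain")
}

#' Conservation profile at interface residues
#'
#' Per-column conservation is `1 -` the Shannon entropy of the 20-letter
#' residue frequencies (gaps excluded) normalised by `log(20)`; columns that
#' are entirely gaps are flagged and score `NA`. For each column the modal
#' residue of the Target and OFF-Target groups is reported (ties joined with
#' `/`).
#'
#' @param alignment Named character vector of aligned rows.
#' @param positions Integer alignment columns of interest.
#' @param target_labels Named logical vector (`TRUE` = Target group), names
#'   matching alignment rows; must contain both groups or only one.
#' @return data.frame: `position`, `conservation`, `all_gap`,
#'   `consensus_target`, `consensus_offtarget`.
#' @export
interface_conservation <- function(alignment, positions, target_labels) {
  m <- .aln_matrix(alignment)
  rownames(m) <- names(alignment)
  if (any(positions < 1 | positions > ncol(m))) {
    stop("positions outside alignment", call. = FALSE)
  }
  lab <- target_labels[names(alignment)]
  modal <- function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    tab <- table(col)
    paste(sort(names(tab)[tab == max(tab)]), collapse = "/")
  }
  rows <- lapply(positions, function(j) {
    col <- m[, j]
    res <- col[col != "-"]
    if (!length(res)) {
      return(data.frame(position = j, conservation = NA_real_, all_gap = TRUE,
                        consensus_target = NA_character_,
                        consensus_offtarget = NA_character_,
                        stringsAsFactors = FALSE))
    }
    p <- table(res) / length(res)
    h <- -sum(p * log(p))
    data.frame(position = j, conservation = 1 - h / log(20), all_gap = FALSE,
               consensus_target = modal(col[which(lab)]),
               consensus_offtarget = modal(col[which(!lab)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
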