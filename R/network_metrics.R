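#' Degree and same-gender fraction of a node
#'
#' Degree counts all neighbours, including alters whose gender is unknown.
#' The same-gender fraction is computed over neighbours with a known gender
#' label only, and is missing (`NA`) for nodes with no such neighbour —
#' never coerced to 0.
#'
#' @param graph undirected igraph graph with vertex attributes `name` and
#'   `gender` (`"F"`, `"M"`, or `NA` for non-participant alters).
#' @param node vertex name.
#' @return `node_degree()`: integer; `same_gender_fraction()`: numeric or
#'   `NA`.
#' @export
node_degree <- function(graph, node) {
  as.integer(igraph::degree(graph, v = node))
}

#' @rdname node_degree
#' @export
same_gender_fraction <- function(graph, node) {
  nb <- igraph::neighbors(graph, node)
  g_nb <- igraph::vertex_attr(graph, "gender", nb)
  g_nb <- g_nb[!is.na(g_nb)]
  if (length(g_nb) == 0) return(NA_real_)
  own <- igraph::vertex_attr(graph, "gender", node)
  mean(g_nb == own)
}

#' Betweenness centrality (unnormalized, undirected, unweighted)
#'
#' \eqn{C_B(i) = \sum_{j \ne k \ne i} n_{jk}(i) / n_{jk}} over unordered
#' node pairs, where \eqn{n_{jk}} is the number of shortest paths between
#' j and k and \eqn{n_{jk}(i)} the number passing through i. Edge weights
#' are deliberately ignored: paths are hop-count shortest paths.
#'
#' @param graph undirected igraph graph.
#' @param nodes vertex names (default: all).
#' @return Named numeric vector of betweenness scores.
#' @export
betweenness_centrality <- function(graph, nodes = igraph::V(graph)) {
  igraph::betweenness(graph, v = nodes, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' Shannon entropy of an ego interaction distribution (bits)
#'
#' \eqn{S_u = -\sum_{i \in N(u)} P_u(i) \log_2 P_u(i)} where \eqn{P_u(i)}
#' is the share of u's interactions going to contact i (interaction counts
#' relative to u's total). High entropy = attention spread evenly over many
#' contacts (less predictable); low entropy = interactions concentrated on
#' few contacts.
#'
#' @param weights positive interaction counts/weights per contact, or an
#'   already-normalized distribution.
#' @return Entropy in bits; `NA` for an empty ego network.
#' @export
interaction_entropy <- function(weights) {
  if (length(weights) == 0) return(NA_real_)
  if (any(weights <= 0)) stop("interaction weights must be positive")
  p <- weights / sum(weights)
  -sum(p * log2(p))
}

#' Count gender-labeled dyad and triad motifs
#'
#' Dyads are edges classified by their endpoint labels (FF, MM, FM); triads
#' are closed triangles classified as all-female, all-male, or mixed. Edges
#' or triangles touching an unlabeled node are an error.
#'
#' @param graph undirected igraph graph with vertex attribute `gender`.
#' @return List with integer vectors `dyads` (`FF`, `MM`, `FM`) and
#'   `triads` (`FFF`, `MMM`, `mixed`).
#' @export
count_motifs <- function(graph) {
  gen <- igraph::V(graph)$gender
  el <- igraph::as_edgelist(graph, names = FALSE)
  g1 <- gen[el[, 1]]; g2 <- gen[el[, 2]]
  if (anyNA(g1) || anyNA(g2))
    stop("count_motifs requires every endpoint to carry a gender label")
  dyads <- c(FF = sum(g1 == "F" & g2 == "F"),
             MM = sum(g1 == "M" & g2 == "M"),
             FM = sum(g1 != g2))
  tri <- igraph::triangles(graph)
  triads <- c(FFF = 0L, MMM = 0L, mixed = 0L)
  if (length(tri) > 0) {
    tm <- matrix(gen[as.integer(tri)], nrow = 3)
    nf <- colSums(tm == "F")
    if (anyNA(nf)) stop("count_motifs requires labeled triangle members")
    triads <- c(FFF = sum(nf == 3L), MMM = sum(nf == 0L),
                mixed = sum(nf == 1L | nf == 2L))
  }
  list(dyads = dyads, triads = triads)
}

#' Fraction of active dyads
#'
#' Ratio between existing and potential links: `|E| / choose(n, 2)`.
#'
#' @param graph igraph graph.
#' @param n_participants number of participants (>= 2) defining the
#'   potential dyads.
#' @return Density in `[0, 1]`.
#' @export
active_dyad_fraction <- function(graph, n_participants) {
  if (n_participants < 2) stop("need at least 2 participants")
  igraph::ecount(graph) / choose(n_participants, 2)
}

#' Mean call duration per ordered gender pair
#'
#' Durations are averaged per (initiator gender, receiver gender). The
#' same-gender strata are direction-symmetric by construction and reported
#' once as `FF` and `MM`; mixed strata are reported as `MF` (male initiates
#' to female) and `FM`.
#'
#' @param events data frame with columns `initiator`, `receiver`,
#'   `duration_s` (call events).
#' @param labels named gender vector indexed by participant id.
#' @return Named numeric vector with entries `FF`, `MM`, `MF`, `FM`
#'   (seconds); `NA` for empty strata.
#' @export
call_duration_stats <- function(events, labels) {
  out <- c(FF = NA_real_, MM = NA_real_, MF = NA_real_, FM = NA_real_)
  if (is.null(events) || nrow(events) == 0) return(out)
  gi <- labels[events$initiator]
  gr <- labels[events$receiver]
  key <- paste0(gi, gr)
  key[key %in% c("FF", "MM")] <- substr(key[key %in% c("FF", "MM")], 1, 2)
  for (k in names(out)) {
    d <- events$duration_s[key == k]
    if (length(d) > 0) out[k] <- mean(d)
  }
  out
}

#' Union of weekly graphs over an aggregation window
#'
#' Collapses the weekly graphs of a channel series over a set of weeks into
#' one labeled graph: an edge exists if the dyad interacted in any of the
#' weeks, with weight = summed weekly weights. Used for month-style
#' aggregated densities and for homophily tests on aggregated structure.
#'
#' @param series a `channel_series`.
#' @param cohort the [cohort()] defining the vertex set.
#' @param weeks week indices to aggregate over (default: all weeks with a
#'   graph).
#' @return igraph graph with vertex attribute `gender`, edge attribute
#'   `weight`.
#' @export
aggregate_graph <- function(series, cohort, weeks = NULL) {
  gs <- series$weekly_graphs
  if (!is.null(weeks)) gs <- gs[names(gs) %in% as.character(weeks)]
  ids <- cohort$participants$id
  if (length(gs) == 0)
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0)),
      directed = FALSE,
      vertices = data.frame(name = ids,
                            gender = cohort$participants$gender)))
  els <- lapply(gs, function(g) {
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1], to = el[, 2],
               weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  })
  el <- do.call(rbind, els)
  el <- el[el$from %in% ids & el$to %in% ids, , drop = FALSE]
  a <- pmin(el$from, el$to); b <- pmax(el$from, el$to)
  w <- rowsum(el$weight, paste(a, b, sep = "\r"))
  parts <- strsplit(rownames(w), "\r", fixed = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = vapply(parts, `[`, "", 1L),
               to = vapply(parts, `[`, "", 2L), weight = w[, 1]),
    directed = FALSE,
    vertices = data.frame(name = ids,
                          gender = cohort$participants$gender))
}

#' Per-participant network indicator table over all channels
#'
#' For each channel, computes weekly per-node degree, same-gender fraction,
#' betweenness and interaction entropy, and averages them per participant
#' over the weeks in which that participant was active. A week in which an
#' active participant has no contacts contributes degree 0 but leaves
#' fraction/entropy undefined for that week. `n_texts` is the weekly
#' number of text messages (summed edge weights), averaged over active
#' weeks.
#'
#' @param cohort a filtered [cohort()].
#' @param networks named list of `channel_series` (one per [CHANNELS]).
#' @param channels channels to include as structural feature columns.
#' @param entropy_channels channels for which interaction entropy is
#'   computed.
#' @return Data frame, rownames = participant id, columns
#'   `<channel>_degree`, `<channel>_same_gender_fraction`,
#'   `<channel>_betweenness`, `<channel>_entropy`, and `text_n_texts`.
#' @export
network_indicator_table <- function(
    cohort, networks,
    channels = c("proximity", "facebook_friend", "call"),
    entropy_channels = c("proximity", "facebook_interaction", "call")) {
  ids <- cohort$participants$id
  n <- length(ids)
  active <- cohort$active_weeks
  out <- data.frame(row.names = ids)

  weekly_avg_matrix <- function(mat) {
    # mat: weeks x ids, NA = undefined; average over each id's active weeks
    vapply(ids, function(id) {
      wk <- intersect(as.character(active[[id]]), rownames(mat))
      if (length(wk) == 0) return(NA_real_)
      weekly_average(mat[wk, id])
    }, numeric(1))
  }

  for (ch in unique(c(channels, entropy_channels))) {
    series <- networks[[ch]]
    weeks <- names(series$weekly_graphs)
    deg <- matrix(NA_real_, length(weeks), n,
                  dimnames = list(weeks, ids))
    sgf <- deg; btw <- deg; ent <- deg
    for (w in weeks) {
      g <- series$weekly_graphs[[w]]
      # restrict to the filtered cohort: excluded participants do not count
      g <- igraph::induced_subgraph(
        g, igraph::V(g)$name[igraph::V(g)$name %in% ids])
      idx <- match(ids, igraph::V(g)$name)
      dv <- igraph::degree(g)
      deg[w, ] <- dv[idx]
      # active participants with no contacts: degree 0 is a real observation
      bv <- igraph::betweenness(g, directed = FALSE, weights = NA)
      btw[w, ] <- bv[idx]
      gen <- igraph::V(g)$gender
      el <- igraph::as_edgelist(g, names = FALSE)
      if (nrow(el) > 0) {
        same <- gen[el[, 1]] == gen[el[, 2]]
        same_cnt <- tabulate(c(el[same, 1], el[same, 2]),
                             nbins = igraph::vcount(g))
        sgf[w, ] <- ifelse(dv[idx] > 0, same_cnt[idx] / dv[idx], NA_real_)
        if (ch %in% entropy_channels) {
          # S_u = log2(W_u) - (1/W_u) * sum_e w_e log2 w_e over incident edges
          wts <- igraph::E(g)$weight
          nv <- igraph::vcount(g)
          ends <- c(el[, 1], el[, 2])
          f <- factor(ends, levels = seq_len(nv))
          wsum <- as.numeric(tapply(c(wts, wts), f, sum))
          wlog <- as.numeric(tapply(c(wts, wts) * log2(c(wts, wts)), f, sum))
          wsum[is.na(wsum)] <- 0
          ev <- ifelse(wsum > 0, log2(wsum) - wlog / wsum, NA_real_)
          ent[w, ] <- ev[idx]
        }
      }
    }
    # weeks where a participant was inactive do not count, incl. degree 0
    if (ch %in% channels) {
      out[[paste0(ch, "_degree")]] <- weekly_avg_matrix(deg)
      out[[paste0(ch, "_same_gender_fraction")]] <- weekly_avg_matrix(sgf)
      out[[paste0(ch, "_betweenness")]] <- weekly_avg_matrix(btw)
    }
    if (ch %in% entropy_channels)
      out[[paste0(ch, "_entropy")]] <- weekly_avg_matrix(ent)
  }

  txt <- networks[["text"]]
  tx <- matrix(NA_real_, length(txt$weekly_graphs), n,
               dimnames = list(names(txt$weekly_graphs), ids))
  for (w in names(txt$weekly_graphs)) {
    g <- txt$weekly_graphs[[w]]
    g <- igraph::induced_subgraph(
      g, igraph::V(g)$name[igraph::V(g)$name %in% ids])
    idx <- match(ids, igraph::V(g)$name)
    stv <- igraph::strength(g, weights = igraph::E(g)$weight)
    tx[w, ] <- stv[idx]
  }
  out[["text_n_texts"]] <- if (nrow(tx) == 0)
    rep(NA_real_, n) else weekly_avg_matrix(tx)
  out
}
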