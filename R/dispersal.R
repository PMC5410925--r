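#' Infer dispersal events from an area-annotated chronogram
#'
#' Every node (tips included) must carry a non-empty area set from an
#' ancestral-range reconstruction.  Along each branch, every area in the
#' child's range but not the parent's is a gain: it yields one event
#' `a -> b` for each area `a` in the parent's range, weighted
#' `1 / |parent range|` so the weights for one gained area sum to 1
#' (`per_source = TRUE` instead counts a full event per source area).
#' Area losses are ignored.
#'
#' @param tree a dated [chronogram()] with `areas` annotations on every
#'   node.
#' @param per_source count 1 per source area instead of splitting the
#'   weight across sources.
#' @return data frame: `parent`, `child`, `from`, `to`, `weight`,
#'   `start_age` (older end of the branch), `end_age`.
#' @export
infer_dispersal_events <- function(tree, per_source = FALSE) {
  chron <- as_chronogram(tree)
  phy <- chron$phy
  ages <- node_ages(chron)
  nn <- ape::Ntip(phy) + phy$Nnode
  areas <- vector("list", nn)
  for (i in seq_len(nrow(chron$data))) {
    a <- chron$data$areas[i]
    if (!is.na(a)) areas[[chron$data$node[i]]] <- strsplit(a, ",", fixed = TRUE)[[1]]
  }
  missing <- which(vapply(areas, function(x) is.null(x) || !length(x), TRUE))
  if (length(missing))
    stop("node(s) without area annotation: ", paste(missing, collapse = ", "))
  out <- list()
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    gained <- setdiff(areas[[ch]], areas[[p]])
    if (!length(gained)) next
    src <- areas[[p]]
    w <- if (per_source) 1 else 1 / length(src)
    for (b in gained) for (a in src)
      out[[length(out) + 1L]] <- data.frame(
        parent = p, child = ch, from = a, to = b, weight = w,
        start_age = ages[p], end_age = ages[ch])
  }
  if (!length(out))
    return(data.frame(parent = integer(), child = integer(),
                      from = character(), to = character(),
                      weight = numeric(), start_age = numeric(),
                      end_age = numeric()))
  do.call(rbind, out)
}

#' Bin dispersal events through time
#'
#' Time bins of width `bin_width` Ma are anchored at the present (0 Ma)
#' and closed on their older edge, tiling `[0, root age]`.  An event on
#' a branch is smeared across the bins in proportion to the length of
#' the branch falling inside each bin (half the branch in a bin counts
#' half an event).  The relative series divides the absolute weighted
#' counts by the total tree branch length per bin, correcting for the
#' growing number of lineages toward the present.
#'
#' @param events event table from [infer_dispersal_events()].
#' @param tree the same dated [chronogram()].
#' @param bin_width bin width in Ma (default 5).
#' @return list: `series` (data frame `bin`, `bin_young`, `bin_old`,
#'   `from`, `to`, `absolute`, `branch_length`, `relative`) and `bins`
#'   (per-bin totals: `bin`, `bin_young`, `bin_old`, `branch_length`,
#'   `absolute`).
#' @export
bin_dispersals <- function(events, tree, bin_width = 5) {
  stopifnot(bin_width > 0)
  chron <- as_chronogram(tree)
  validate_chronogram(chron)
  ages <- node_ages(chron)
  root_age <- max(ages)
  n_bins <- max(1L, ceiling(root_age / bin_width - 1e-12))
  lo <- (seq_len(n_bins) - 1) * bin_width
  hi <- seq_len(n_bins) * bin_width
  overlap <- function(young, old) {
    pmax(0, pmin(old, hi) - pmax(young, lo))
  }
  # total branch length per bin
  bin_len <- numeric(n_bins)
  phy <- chron$phy
  for (e in seq_len(nrow(phy$edge)))
    bin_len <- bin_len + overlap(ages[phy$edge[e, 2]], ages[phy$edge[e, 1]])
  pairs <- unique(events[, c("from", "to")])
  series <- list()
  for (i in seq_len(nrow(pairs))) {
    sel <- events$from == pairs$from[i] & events$to == pairs$to[i]
    abs_w <- numeric(n_bins)
    for (j in which(sel)) {
      blen <- events$start_age[j] - events$end_age[j]
      frac <- if (blen > 0) overlap(events$end_age[j], events$start_age[j]) / blen
      else as.numeric(events$end_age[j] > lo & events$end_age[j] <= hi |
                        (events$end_age[j] == 0 & lo == 0))
      abs_w <- abs_w + events$weight[j] * frac
    }
    series[[i]] <- data.frame(
      bin = seq_len(n_bins), bin_young = lo, bin_old = hi,
      from = pairs$from[i], to = pairs$to[i],
      absolute = abs_w, branch_length = bin_len,
      relative = ifelse(bin_len > 0, abs_w / bin_len, 0))
  }
  totals <- data.frame(bin = seq_len(n_bins), bin_young = lo, bin_old = hi,
                       branch_length = bin_len,
                       absolute = if (length(series))
                         Reduce(`+`, lapply(series, `[[`, "absolute"))
                       else rep(0, n_bins))
  list(series = if (length(series)) do.call(rbind, series) else
    data.frame(bin = integer(), bin_young = numeric(), bin_old = numeric(),
               from = character(), to = character(), absolute = numeric(),
               branch_length = numeric(), relative = numeric()),
    bins = totals)
}
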