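# Duplication-event inference from a pairwise age matrix.
#
# Under a molecular clock the pairwise ages are (noisy) ultrametric
# distances, and average-linkage agglomeration (UPGMA) is the canonical way
# to read off the sequence of duplication events: each merge is one event
# whose time is the linkage age directly (the halving is already done in the
# clock conversion, since ages are in years per lineage pair). Deviations
# from ultrametricity are reported as a coefficient of variation, never
# silently repaired.

#' Infer ordered duplication events from a pairwise age matrix
#'
#' Average-linkage (UPGMA) agglomeration with a deterministic tie-break:
#' among equally close pairs the one whose lexicographically smallest member
#' name is smallest (then the next member name) is merged first.
#'
#' @param age_matrix symmetric non-negative matrix of ages in years, zero
#'   diagonal.
#' @param gene_names leaf names; defaults to the matrix dimnames.
#' @return object of class `serk_duplication_history` with `events` (data
#'   frame `time_years`, `clade` of merged members, `cv` of the within-merge
#'   pairwise ages), `tree` (nested node list with heights in years) and
#'   `ultrametricity_cv` (largest per-event cv).
#' @export
infer_events <- function(age_matrix, gene_names = rownames(age_matrix)) {
  m <- as.matrix(age_matrix)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(nrow(m)))
  if (nrow(m) < 2L) stop("need at least two genes")
  if (any(is.na(m)) || any(m < 0)) stop("age matrix has NaN/negative entries")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(m)))
    stop("age matrix is not symmetric")
  dimnames(m) <- list(gene_names, gene_names)

  clusters <- lapply(gene_names, function(g)
    list(members = g, height = 0, node = list(label = g, height = 0,
                                              children = NULL)))
  sizes <- rep(1L, length(clusters))
  d <- m
  events <- list()

  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        cand <- list(i = i, j = j, dist = d[i, j],
                     key = sort(c(sort(clusters[[i]]$members)[1L],
                                  sort(clusters[[j]]$members)[1L])))
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             paste(cand$key, collapse = "\r") <
             paste(best$key, collapse = "\r")))
          best <- cand
      }
    }
    i <- best$i; j <- best$j
    ci <- clusters[[i]]; cj <- clusters[[j]]
    within <- as.vector(m[ci$members, cj$members])
    cv <- if (length(within) > 1L && mean(within) > 0)
      sd(within) / mean(within) else 0
    merged_members <- sort(c(ci$members, cj$members))
    events[[length(events) + 1L]] <- list(
      time_years = best$dist, clade = merged_members, cv = cv)
    node <- list(label = NULL, height = best$dist,
                 children = list(ci$node, cj$node))
    # average-linkage distance update
    newd <- rep(NA_real_, k)
    for (l in seq_len(k)) {
      if (l %in% c(i, j)) next
      newd[l] <- (sizes[i] * d[i, l] + sizes[j] * d[j, l]) /
        (sizes[i] + sizes[j])
    }
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    clusters <- c(clusters[keep],
                  list(list(members = merged_members, height = best$dist,
                            node = node)))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }

  ev <- data.frame(
    event = seq_along(events),
    time_years = vapply(events, `[[`, numeric(1), "time_years"),
    clade = vapply(events, function(e) paste(e$clade, collapse = ","),
                   character(1)),
    cv = vapply(events, `[[`, numeric(1), "cv"),
    stringsAsFactors = FALSE)
  if (is.unsorted(ev$time_years))
    warning("merge heights are not monotone: age matrix departs strongly ",
            "from ultrametricity")
  structure(list(events = ev, tree = clusters[[1L]]$node,
                 gene_names = gene_names,
                 ultrametricity_cv = max(ev$cv)),
            class = "serk_duplication_history")
}

#' @export
print.serk_duplication_history <- function(x, ...) {
  cat("Duplication history:", nrow(x$events), "events over",
      length(x$gene_names), "genes\n")
  ev <- x$events
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  event %d: %.3g Myr  {%s}\n", i, ev$time_years[i] / 1e6,
                ev$clade[i]))
  invisible(x)
}

#' Serialise a duplication history as Newick text
#'
#' Branch lengths are in millions of years; the tree is ultrametric by
#' construction (every leaf-to-root path length equals the root event time).
#'
#' @param history a `serk_duplication_history`.
#' @param digits significant digits for branch lengths.
#' @return single Newick string, terminated by `;`.
#' @export
to_newick <- function(history, digits = 10L) {
  stopifnot(inherits(history, "serk_duplication_history"))
  fmt <- function(x) sprintf("%.*g", digits, x / 1e6)
  recurse <- function(node, parent_height) {
    bl <- fmt(parent_height - node$height)
    if (is.null(node$children))
      paste0(node$label, ":", bl)
    else
      paste0("(", paste(vapply(node$children, recurse, character(1),
                               parent_height = node$height),
                        collapse = ","), "):", bl)
    }
  root <- history$tree
  inner <- paste(vapply(root$children, recurse, character(1),
                        parent_height = root$height), collapse = ",")
  paste0("(", inner, ");")
}

#' Convert a duplication history to an ape phylo tree
#'
#' @param history a `serk_duplication_history`.
#' @return an [ape::read.tree()]-parsed `phylo` object (edge lengths in Myr).
#' @export
history_as_phylo <- function(history) {
  ape::read.tree(text = to_newick(history))
}
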