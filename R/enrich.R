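#' Hypergeometric upper-tail probability
#'
#' Exact over-representation p-value `P(X >= k)` for drawing `k` or more
#' members of a `K`-element category when sampling `n` features from a
#' universe of `N`, computed by log-space summation of the hypergeometric
#' pmf (`lchoose` terms combined with a log-sum-exp), so tiny tails keep
#' full relative precision.
#'
#' @param k observed overlap count.
#' @param K category size in the universe.
#' @param n query size.
#' @param N universe size.
#' @param ease if `TRUE`, compute the more conservative jackknifed variant
#'   that removes one overlapping member (tail at `max(k - 1, 0)`).
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N, ease = FALSE) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K < 0 || n < 0 || N < 0 || K > N || n > N) {
    stop("need 0 <= K, n <= N")
  }
  if (k < 0 || k > min(K, n)) stop("need 0 <= k <= min(K, n)")
  if (ease) k <- max(k - 1, 0)
  if (k <= max(0, n - (N - K))) return(1)   # whole support: p = 1 exactly
  j <- seq(k, min(K, n))
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lp)
  p <- exp(m + log(sum(exp(lp - m))))
  min(p, 1)
}

#' Read a GMT-like term-set file
#'
#' Each tab-separated line is `term_id`, `term_name`, then member feature
#' names.
#'
#' @param path file path.
#' @return named list of term sets, each
#'   `list(term_id, term_name, members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", l)
    list(term_id = f[1], term_name = f[2], members = unique(f[-(1:2)]))
  })
  names(terms) <- vapply(terms, `[[`, "", "term_id")
  terms
}

#' Term over-representation analysis of a feature set
#'
#' One hypergeometric upper-tail test per term: `k` = query members in the
#' term, `K` = universe members in the term, `n` = query size, `N` =
#' universe size.  Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw ones.
#'
#' @param query character vector of features of interest (must be a
#'   non-empty subset of `universe`).
#' @param universe background feature set.
#' @param terms a [read_gmt()] list (or a named list of member vectors).
#' @param ease see [hypergeom_upper_tail()].
#' @return `data.frame` sorted by ascending p-value: `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`.
#' @export
term_enrichment <- function(query, universe, terms, ease = FALSE) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe)) {
    stop("query features outside the universe: ",
         paste(setdiff(query, universe), collapse = ", "))
  }
  terms <- lapply(seq_along(terms), function(i) {
    t <- terms[[i]]
    if (!is.list(t)) t <- list(term_id = names(terms)[i] %||% sprintf("T%03d", i),
                               term_name = names(terms)[i] %||% "", members = t)
    t
  })
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(t) {
    members <- intersect(unique(t$members), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(term_id = t$term_id, term_name = t$term_name,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N, ease = ease),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two binary membership vectors
#'
#' Chance-corrected agreement computed from the 2x2 contingency of the two
#' vectors: `(p_o - p_e) / (1 - p_e)`.  Identical vectors with degenerate
#' margins (`p_e = 1`) are defined as kappa 1.
#'
#' @param a,b logical/0-1 vectors of equal length >= 1.
#' @return kappa in [-1, 1].
#' @export
kappa_similarity <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("membership vectors differ in length")
  if (length(a) == 0L) stop("empty membership vectors")
  t <- length(a)
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  p_o <- (n11 + n00) / t
  p_e <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / t^2
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Kappa-similarity annotation clustering with a representative-term rule
#'
#' Groups terms by single linkage over pairwise kappa similarity of their
#' membership vectors (connected components of the `kappa >= threshold`
#' graph).  Clusters whose best member p-value is not below 0.05 are
#' discarded; each surviving cluster is represented by its lowest-p member
#' (ties broken lexicographically by term id) and scored by the negative
#' mean log10 p of its members.
#'
#' @param records a [term_enrichment()] table.
#' @param memberships named list mapping `term_id` to member feature
#'   vectors, or a logical matrix (features x terms).
#' @param kappa_threshold single-linkage similarity cutoff (default 0.5).
#' @param p_cutoff representative significance bound (default 0.05,
#'   strict `<`).
#' @return `data.frame` sorted by representative term id: `cluster`,
#'   `representative_term_id`, `representative_p`, `enrichment_score`,
#'   `n_terms`, `member_term_ids` (comma-separated, sorted).
#' @export
cluster_annotations <- function(records, memberships, kappa_threshold = 0.5,
                                p_cutoff = 0.05) {
  ids <- sort(unique(records$term_id))
  if (is.matrix(memberships)) {
    mat <- memberships[, ids, drop = FALSE] != 0
  } else {
    feats <- sort(unique(unlist(memberships[ids])))
    mat <- sapply(ids, function(id) feats %in% memberships[[id]])
    if (length(feats) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, ids))
  }
  m <- length(ids)
  # single linkage = connected components of the thresholded kappa graph
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      if (kappa_similarity(mat[, i], mat[, j]) >= kappa_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(m), find, 1L)
  p_of <- setNames(records$p_value, records$term_id)
  clusters <- lapply(split(ids, comp), function(members) {
    p <- p_of[members]
    best <- min(p)
    if (best >= p_cutoff) return(NULL)
    rep_id <- sort(members[p == best])[1]
    data.frame(representative_term_id = rep_id,
               representative_p = unname(best),
               enrichment_score = -mean(log10(p)),
               n_terms = length(members),
               member_term_ids = paste(sort(members), collapse = ","),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, clusters[!vapply(clusters, is.null, TRUE)])
  if (is.null(clusters)) {
    return(data.frame(cluster = integer(), representative_term_id = character(),
                      representative_p = numeric(), enrichment_score = numeric(),
                      n_terms = integer(), member_term_ids = character(),
                      stringsAsFactors = FALSE))
  }
  clusters <- clusters[order(clusters$representative_term_id), , drop = FALSE]
  clusters <- cbind(cluster = seq_len(nrow(clusters)), clusters)
  rownames(clusters) <- NULL
  clusters
}
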