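#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic preranked running-sum statistic: walking down the ranked list,
#' member ("hit") positions increment the sum by `|score|^p / sum_hits
#' |score|^p` and non-member positions decrement it by `1 / (N - N_hit)`.
#' The enrichment score is the running-sum value of maximal absolute
#' deviation from zero; the leading edge comprises the members at or before
#' the extremum (at or after it, for a negative score).
#'
#' @param ranked named numeric vector of ranking scores sorted in
#'   decreasing order (names are gene ids; ties must already be broken).
#' @param members character vector of member gene ids.
#' @param weight_exponent the exponent `p` (default 1; 0 gives the
#'   unweighted KS statistic).
#' @return list: `es`, `running_sum` (length N), `leading_edge`
#'   (character), `size_used`.
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1) {
  genes <- names(ranked)
  if (is.null(genes) || anyDuplicated(genes)) {
    abort("`ranked` must be a named vector with unique gene ids.")
  }
  hit <- genes %in% members
  n_hit <- sum(hit)
  n <- length(ranked)
  if (n_hit == 0) abort("No gene-set member present in the ranking.")
  if (n_hit == n) abort("Gene set covers the whole ranking (no misses).")
  w <- abs(ranked)^weight_exponent
  denom_hit <- sum(w[hit])
  incr <- rep(-1 / (n - n_hit), n)
  if (denom_hit == 0) {
    # all member scores zero: fall back to equal hit weights
    incr[hit] <- 1 / n_hit
  } else {
    incr[hit] <- w[hit] / denom_hit
  }
  rs <- cumsum(incr)
  imax <- which.max(abs(rs))
  es <- rs[imax]
  leading <- if (es >= 0) {
    genes[hit & seq_len(n) <= imax]
  } else {
    genes[hit & seq_len(n) >= imax]
  }
  list(es = es, running_sum = rs, leading_edge = leading,
       size_used = n_hit)
}

#' Null enrichment-score distribution by gene permutation
#'
#' Scores uniformly random member sets of a fixed size against the fixed
#' ranking; this is the standard gene-permutation null for preranked
#' enrichment analysis.
#'
#' @param ranked named numeric vector as in [enrichment_score()].
#' @param set_size size of each random set (must be < N).
#' @param n_permutations number of draws (>= 100).
#' @param weight_exponent exponent passed to the score.
#' @param seed optional integer seed.
#' @return numeric vector of null enrichment scores.
#' @export
null_es_distribution <- function(ranked, set_size, n_permutations = 1000,
                                 weight_exponent = 1, seed = NULL) {
  if (n_permutations < 100) abort("Use at least 100 permutations.")
  n <- length(ranked)
  if (set_size >= n) abort("set_size must be smaller than the ranking.")
  if (set_size == n - 1) {
    inform("set_size = N - 1: near-degenerate null (single miss).")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- abs(ranked)^weight_exponent
  vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n, set_size)
    hit_w <- w[idx]
    denom <- sum(hit_w)
    incr <- rep(-1 / (n - set_size), n)
    incr[idx] <- if (denom == 0) 1 / set_size else hit_w / denom
    rs <- cumsum(incr)
    rs[which.max(abs(rs))]
  }, numeric(1))
}

#' Preranked gene set enrichment analysis
#'
#' Scores every gene set of a collection against a ranked list, normalizes
#' each enrichment score by the mean |null score| of matching sign
#' (gene-permutation null, cached per set size), and reports an add-one
#' permutation p-value, BH adjustment across sets, and a GSEA-style FDR q
#' from the pooled normalized null. A set is flagged `enriched` when
#' `p_adj <= 0.25` and `|nes| >= 1`.
#'
#' @param ranking tibble with columns `gene` and `score`, or a named
#'   numeric vector. Ties are broken by gene id for determinism.
#' @param collection named list of member vectors (see [read_gmt()]).
#' @param weight_exponent score exponent (default 1).
#' @param n_permutations permutations per distinct set size (default 1000).
#' @param min_size,max_size set-size bounds applied after intersecting with
#'   the ranking (defaults 10 and 500).
#' @param seed optional integer seed for the permutation null.
#' @return tibble: `set_name`, `es`, `nes`, `p_perm`, `p_adj`, `fdr_q`,
#'   `size_used`, `gene_ratio`, `leading_edge` (pipe-separated), `enriched`.
#' @export
preranked_gsea <- function(ranking, collection, weight_exponent = 1,
                           n_permutations = 1000, min_size = 10,
                           max_size = 500, seed = NULL) {
  if (is.data.frame(ranking)) {
    check_columns(ranking, c("gene", "score"), "ranking")
    ranked <- setNames(ranking$score, ranking$gene)
  } else {
    ranked <- ranking
  }
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  genes <- names(ranked)

  sizes <- vapply(collection, function(m) length(intersect(m, genes)),
                  integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(collection)[!keep]
  if (length(skipped) > 0) {
    inform(paste0("Skipped ", length(skipped),
                  " set(s) outside size bounds after intersection."))
  }
  collection <- collection[keep]
  sizes <- sizes[keep]
  if (length(collection) == 0) abort("No gene set within the size bounds.")

  if (!is.null(seed)) set.seed(as.integer(seed))
  nulls <- lapply(sort(unique(sizes)), function(s) {
    null_es_distribution(ranked, s, n_permutations,
                         weight_exponent = weight_exponent)
  })
  names(nulls) <- as.character(sort(unique(sizes)))

  res <- purrr::map_dfr(names(collection), function(nm) {
    sc <- enrichment_score(ranked, collection[[nm]], weight_exponent)
    null <- nulls[[as.character(sc$size_used)]]
    same <- null[sign(null) == sign(sc$es)]
    mean_abs <- mean(abs(same))
    nes <- if (length(same) > 0 && mean_abs > 0) sc$es / mean_abs else 0
    p_perm <- (1 + sum(abs(same) >= abs(sc$es))) / (1 + length(same))
    tibble::tibble(
      set_name = nm, es = sc$es, nes = nes, p_perm = p_perm,
      size_used = sc$size_used,
      gene_ratio = length(sc$leading_edge) / sc$size_used,
      leading_edge = paste(sc$leading_edge, collapse = "|")
    )
  })
  # normalized null pooled over set sizes, for the GSEA-style FDR q
  null_nes <- unlist(lapply(names(nulls), function(s) {
    v <- nulls[[s]]
    pos <- mean(abs(v[v >= 0]))
    neg <- mean(abs(v[v < 0]))
    out <- v
    if (is.finite(pos) && pos > 0) out[v >= 0] <- v[v >= 0] / pos
    if (is.finite(neg) && neg > 0) out[v < 0] <- v[v < 0] / neg
    out
  }), use.names = FALSE)
  res$fdr_q <- gsea_fdr_q(res$nes, null_nes)
  res$p_adj <- adjust_fdr(res$p_perm, "bh")
  res$enriched <- res$p_adj <= 0.25 & abs(res$nes) >= 1
  res[c("set_name", "es", "nes", "p_perm", "p_adj", "fdr_q", "size_used",
        "gene_ratio", "leading_edge", "enriched")]
}

# ratio of null to observed tail proportions at each NES, by sign
gsea_fdr_q <- function(nes, null_nes) {
  q <- rep(NA_real_, length(nes))
  for (i in seq_along(nes)) {
    v <- nes[i]
    if (v >= 0) {
      null_tail <- mean(null_nes[null_nes >= 0] >= v)
      obs_tail <- mean(nes[nes >= 0] >= v)
    } else {
      null_tail <- mean(null_nes[null_nes < 0] <= v)
      obs_tail <- mean(nes[nes < 0] <= v)
    }
    q[i] <- if (is.finite(null_tail) && obs_tail > 0) {
      min(1, null_tail / obs_tail)
    } else {
      NA_real_
    }
  }
  # enforce monotonicity in |nes| within each sign
  for (s in c(1, -1)) {
    idx <- if (s > 0) which(nes >= 0) else which(nes < 0)
    if (length(idx) > 1) {
      ord <- idx[order(-abs(nes[idx]))]
      q[ord] <- cummax(pmin(q[ord], 1))
    }
  }
  q
}
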