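#' Cluster dose-response AUGC profiles
#'
#' Agglomerative clustering of strain dose-response vectors under the
#' Chebyshev (L-infinity) metric with average linkage, cut at `k` clusters.
#' The L-infinity metric keys on the dose of largest deviation, which is
#' what separates behaviors that agree at most doses but diverge at the
#' extremes (no inducer, or saturating inducer). Cluster indices are
#' renumbered by decreasing cluster-mean value at the lowest dose so that
#' runs are reproducible and the constitutive-like cluster comes first.
#' Strains are processed in `strain_id` order, making the result invariant
#' to input row order.
#'
#' @param mat an [compute_augc_matrix()] matrix, or any strains x doses
#'   matrix with strain rownames and dose colnames; missing cells are
#'   imputed from the nearest dose.
#' @param k number of clusters.
#' @param metric only `"chebyshev"` is supported.
#' @param linkage hclust linkage method.
#' @param label_args arguments forwarded to [label_behavior()].
#' @return data.frame of class `behavior_profiles` with `strain_id`,
#'   `cluster`, `behavior`; attributes `profiles` (imputed matrix),
#'   `cluster_means`, `hclust` and `order` (dendrogram order of strains).
#' @export
cluster_profiles <- function(mat, k = 5L, metric = "chebyshev",
                             linkage = "average", label_args = list()) {
    mat <- as.matrix(mat)
    if (k < 2L) stop("k must be at least 2")
    if (k > nrow(mat)) stop("k exceeds the number of strains")
    metric <- match.arg(metric, "chebyshev")
    mat <- mat[order(rownames(mat)), , drop = FALSE]
    mat <- t(apply(mat, 1L, impute_nearest))
    if (anyNA(mat)) stop("profiles with no finite values cannot be clustered")

    d <- dist(mat, method = "maximum")  # Chebyshev / L-infinity
    hc <- hclust(d, method = linkage)
    raw <- cutree(hc, k = k)

    means <- vapply(seq_len(k), function(cl)
        colMeans(mat[raw == cl, , drop = FALSE]), numeric(ncol(mat)))
    means <- t(means)  # k x doses
    ord <- order(means[, 1L], decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    cluster <- relabel[raw]
    means <- means[ord, , drop = FALSE]
    rownames(means) <- seq_len(k)

    doses <- suppressWarnings(as.numeric(colnames(mat)))
    labels <- do.call(label_behavior,
                      c(list(cluster_means = means, doses = doses), label_args))
    res <- data.frame(strain_id = rownames(mat), cluster = cluster,
                      behavior = labels[cluster], stringsAsFactors = FALSE)
    structure(res, class = c("behavior_profiles", "data.frame"),
              profiles = mat, cluster_means = means, hclust = hc,
              order = rownames(mat)[hc$order])
}

impute_nearest <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(is.finite(v))
    if (!length(ok)) return(v)
    for (i in which(!is.finite(v)))
        v[i] <- v[ok[which.min(abs(ok - i))]]
    v
}

#' Label cluster mean dose-response profiles with behavior classes
#'
#' Rule-based reading of a reference-scaled mean profile over increasing
#' doses: profiles that never rise above `low_threshold` are
#' `nonfunctional`; profiles starting below `low_threshold` at the lowest
#' dose are inducer-`dependent`, and `dependent_toxic` when they fall from
#' their peak by more than `drop_threshold`; profiles starting high are
#' `constitutive`, or `constitutive_toxic` when they show the same
#' high-dose fall. A profile with no finite values is `unclassified`.
#'
#' @param cluster_means k x doses matrix of mean profiles.
#' @param doses increasing dose grid (only its order is used).
#' @param low_threshold "low growth" cutoff, as a fraction of the
#'   reference.
#' @param drop_threshold fractional fall from the peak that counts as
#'   toxicity.
#' @return character vector of length k.
#' @export
label_behavior <- function(cluster_means, doses = NULL, low_threshold = 0.2,
                           drop_threshold = 0.3) {
    cluster_means <- as.matrix(cluster_means)
    if (!is.null(doses) && is.unsorted(doses))
        stop("doses must be increasing")
    apply(cluster_means, 1L, function(m) {
        m <- m[is.finite(m)]
        if (!length(m)) return("unclassified")
        peak <- max(m)
        if (peak < low_threshold) return("nonfunctional")
        falls <- (peak - m[length(m)]) / peak > drop_threshold
        if (m[1L] < low_threshold) {
            if (falls) "dependent_toxic" else "dependent"
        } else {
            if (falls) "constitutive_toxic" else "constitutive"
        }
    })
}

#' @export
print.behavior_profiles <- function(x, ...) {
    cat("Behavior profiles:", nrow(x), "strains in",
        length(unique(x$cluster)), "clusters\n")
    print(table(x$behavior))
    invisible(x)
}
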