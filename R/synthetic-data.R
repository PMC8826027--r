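#' Specification of a synthetic planted-complex study
#'
#' Describes the generative model used for self-contained testing: a
#' background random graph with planted dense complexes, expression
#' values driven by latent per-complex activities, and class labels that
#' shift the activity means. The defaults define a moderately hard
#' three-class problem: 300 genes, 12 planted complexes of 6-15 genes,
#' within-complex edge probability 0.9 over a 0.01 background, 400
#' samples and class effects of two latent standard deviations against
#' observation noise of 0.5.
#'
#' @param n_genes total number of genes.
#' @param n_complexes number of planted complexes.
#' @param complex_size_range inclusive `(min, max)` complex size.
#' @param p_in within-complex edge probability.
#' @param p_out background edge probability (`p_out <= p_in`).
#' @param overlap_fraction fraction of complexes that share one gene
#'   with an earlier complex.
#' @param activity_loading_scale loading of a member gene on its
#'   complex's latent activity.
#' @param noise_sd standard deviation of per-gene observation noise.
#' @param n_classes number of phenotype classes.
#' @param n_samples number of samples (`>= 2 * n_classes`).
#' @param class_effect_scale standard deviation of the class-specific
#'   latent activity means.
#' @param seed master integer seed; sub-generators draw from seeds
#'   derived as `seed + 1` (network) and `seed + 2` (expression), so each
#'   stage is independently reproducible.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 300L, n_complexes = 12L,
                           complex_size_range = c(6L, 15L),
                           p_in = 0.9, p_out = 0.01,
                           overlap_fraction = 0.25,
                           activity_loading_scale = 1,
                           noise_sd = 0.5,
                           n_classes = 3L, n_samples = 400L,
                           class_effect_scale = 2,
                           seed = 1L) {
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in,
            complex_size_range[1] >= 2,
            complex_size_range[2] >= complex_size_range[1],
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_sd >= 0, n_classes >= 2,
            n_samples >= 2 * n_classes)
  structure(list(n_genes = as.integer(n_genes),
                 n_complexes = as.integer(n_complexes),
                 complex_size_range = as.integer(complex_size_range),
                 p_in = p_in, p_out = p_out,
                 overlap_fraction = overlap_fraction,
                 activity_loading_scale = activity_loading_scale,
                 noise_sd = noise_sd,
                 n_classes = as.integer(n_classes),
                 n_samples = as.integer(n_samples),
                 class_effect_scale = class_effect_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random network with planted complexes
#'
#' Genes are assigned to `n_complexes` planted complexes (a fraction of
#' which share one gene with an earlier complex); every within-complex
#' gene pair is connected with probability `p_in` and every other pair
#' with probability `p_out`. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (an [igraph::igraph] over all genes,
#'   isolated genes included) and `ground_truth` (the planted membership
#'   as a [clustering()] with algorithm tag `"planted"`).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed + 1L, {
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    sizes <- sample(seq.int(spec$complex_size_range[1],
                            spec$complex_size_range[2]),
                    spec$n_complexes, replace = TRUE)
    overlapping <- rep(FALSE, spec$n_complexes)
    if (spec$n_complexes > 1L && spec$overlap_fraction > 0) {
      n_ov <- round(spec$overlap_fraction * (spec$n_complexes - 1L))
      if (n_ov > 0) {
        overlapping[sample(2:spec$n_complexes, n_ov)] <- TRUE
      }
    }
    n_fresh <- sum(sizes) - sum(overlapping)
    if (n_fresh > spec$n_genes) {
      stop("infeasible sizes: planted complexes need ", n_fresh,
           " distinct genes but only ", spec$n_genes, " exist")
    }
    unassigned <- genes
    assigned <- character(0)
    complexes <- vector("list", spec$n_complexes)
    for (i in seq_len(spec$n_complexes)) {
      members <- character(0)
      if (overlapping[i]) {
        members <- sample(assigned, 1L)
      }
      fresh <- sample(unassigned, sizes[i] - length(members))
      members <- c(members, fresh)
      unassigned <- setdiff(unassigned, fresh)
      assigned <- union(assigned, members)
      complexes[[i]] <- sort(members)
    }
    names(complexes) <- sprintf("planted_%02d", seq_len(spec$n_complexes))

    # edge sampling over all gene pairs
    pairs <- utils::combn(genes, 2L)
    in_complex <- rep(FALSE, ncol(pairs))
    for (members in complexes) {
      in_complex <- in_complex |
        (pairs[1L, ] %in% members & pairs[2L, ] %in% members)
    }
    p <- ifelse(in_complex, spec$p_in, spec$p_out)
    keep <- stats::rbinom(length(p), 1L, p) == 1L
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, spec$n_genes, name = genes)
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    }
    list(network = g,
         ground_truth = clustering(complexes, algorithm = "planted",
                                   params = unclass(spec)))
  })
}

#' Generate expression data and labels from planted complexes
#'
#' Samples receive balanced class labels. For every class and complex a
#' latent mean is drawn once from `N(0, class_effect_scale^2)`; each
#' sample's complex activity is `N(mean_class_complex, 1)` and a member
#' gene's expression is the sum of its complexes' activities times
#' `activity_loading_scale` plus `N(0, noise_sd^2)` noise. Genes in no
#' complex are pure noise. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param ground_truth the planted [clustering()] from
#'   [generate_planted_network()].
#' @return an [expression_dataset()] with labels `class_1..class_C` and
#'   an attribute `latent_activities` (n_samples x n_complexes matrix).
#' @export
generate_expression_phenotype <- function(spec, ground_truth) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(ground_truth, "clustering"))
  withr_seed(spec$seed + 2L, {
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    m <- spec$n_samples
    classes <- paste0("class_", seq_len(spec$n_classes))
    labels <- factor(rep(classes, length.out = m)[sample.int(m)],
                     levels = classes)
    cx <- ground_truth$clusters
    l <- length(cx)

    class_means <- matrix(stats::rnorm(spec$n_classes * l,
                                       sd = spec$class_effect_scale),
                          spec$n_classes, l)
    z <- matrix(stats::rnorm(m * l), m, l) +
      class_means[as.integer(labels), , drop = FALSE]
    colnames(z) <- names(cx)

    X <- matrix(stats::rnorm(m * spec$n_genes, sd = spec$noise_sd),
                m, spec$n_genes, dimnames = list(NULL, genes))
    for (i in seq_len(l)) {
      members <- cx[[i]]
      X[, members] <- X[, members] +
        spec$activity_loading_scale * z[, i]
    }
    ds <- expression_dataset(X, gene_names = genes,
                             sample_ids = sprintf("s%04d", seq_len(m)),
                             labels = labels)
    attr(ds, "latent_activities") <- z
    ds
  })
}
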