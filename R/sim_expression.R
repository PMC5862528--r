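#' Count-simulation parameters
#'
#' Design for synthetic gene-by-sample negative-binomial count matrices
#' carrying the study's signature structure: an embryonic transcription
#' factor module up-regulated in both tumor and embryo samples, and a
#' neural differentiation module expressed in disc-like tissues but
#' down-shifted in tumors (and absent in embryos, which have not yet turned
#' on the neural program). The default module sizes sum to 124 genes, the
#' size of the TF signature used for clustering.
#'
#' @param n_genes total number of genes.
#' @param groups named integer vector: samples per group. Groups named
#'   `"tumor"` or `"embryo"` carry the embryonic module up-shift; all other
#'   groups are disc-like.
#' @param embryonic_module_size,neural_module_size module sizes; their sum
#'   must not exceed `n_genes`.
#' @param log2fc_embryonic up-shift of the embryonic module in tumor/embryo
#'   samples (log2 units, >= 0 expected).
#' @param log2fc_neural shift of the neural module in tumor and embryo
#'   samples relative to disc-like baseline (negative = down).
#' @param dispersion NB dispersion alpha (> 0); variance = m + alpha m^2.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the
#'   per-gene baseline means.
#' @param library_size_range uniform range of per-sample library factors.
#' @return Object of class `count_sim_params`.
#' @export
count_sim_params <- function(n_genes = 2000L,
                             groups = c(embryo = 10L, eye_disc = 10L,
                                        tumor = 7L, control = 4L, other = 8L),
                             embryonic_module_size = 60L,
                             neural_module_size = 64L,
                             log2fc_embryonic = 3,
                             log2fc_neural = -3,
                             dispersion = 0.1,
                             base_mean_meanlog = log(100),
                             base_mean_sdlog = 1.2,
                             library_size_range = c(0.7, 1.3)) {
  n_genes <- as.integer(n_genes)
  if (is.null(names(groups)) || any(names(groups) == "") ||
      length(groups) < 2L || any(groups < 2L)) {
    stop("`groups` must be a named vector of >= 2 groups with >= 2 samples each",
         call. = FALSE)
  }
  if (embryonic_module_size + neural_module_size > n_genes) {
    stop("module sizes exceed `n_genes`", call. = FALSE)
  }
  if (!is.finite(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be > 0", call. = FALSE)
  }
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      diff(library_size_range) < 0) {
    stop("`library_size_range` must be a positive interval", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, groups = groups,
         embryonic_module_size = as.integer(embryonic_module_size),
         neural_module_size = as.integer(neural_module_size),
         log2fc_embryonic = log2fc_embryonic, log2fc_neural = log2fc_neural,
         dispersion = dispersion, base_mean_meanlog = base_mean_meanlog,
         base_mean_sdlog = base_mean_sdlog,
         library_size_range = library_size_range),
    class = "count_sim_params")
}

#' Simulate a signature-structured count matrix
#'
#' Counts are NB(mean = base mean x library factor x 2^(signed shift),
#' dispersion alpha) with shifts as described in [count_sim_params()].
#'
#' @param params a [count_sim_params()] object.
#' @param seed integer seed; the generator is a pure function of
#'   `(params, seed)`.
#' @return List with `counts` (integer matrix, genes x samples), `samples`
#'   (data frame: `sample`, `group`) and `genes` (data frame: `gene`,
#'   `module` in embryonic/neural/none).
#' @export
simulate_expression <- function(params, seed) {
  if (!inherits(params, "count_sim_params")) {
    stop("`params` must be a count_sim_params object", call. = FALSE)
  }
  with_seed(seed, {
    g <- params$n_genes
    groups <- params$groups
    n_samples <- sum(groups)
    group_of <- rep(names(groups), groups)
    sample_ids <- sprintf("%s_%d", group_of,
                          unlist(lapply(groups, seq_len), use.names = FALSE))
    module <- rep("none", g)
    module[seq_len(params$embryonic_module_size)] <- "embryonic"
    module[params$embryonic_module_size +
             seq_len(params$neural_module_size)] <- "neural"
    base_mean <- stats::rlnorm(g, params$base_mean_meanlog,
                               params$base_mean_sdlog)
    libf <- stats::runif(n_samples, params$library_size_range[1],
                         params$library_size_range[2])
    embryonic_like <- group_of %in% c("tumor", "embryo")
    shift <- matrix(0, g, n_samples)
    shift[module == "embryonic", embryonic_like] <- params$log2fc_embryonic
    # neural module: disc-like baseline; down-shifted in tumor and embryo
    shift[module == "neural", embryonic_like] <- params$log2fc_neural
    mu <- (base_mean %o% libf) * 2^shift
    counts <- matrix(stats::rnbinom(g * n_samples, mu = mu,
                                    size = 1 / params$dispersion),
                     g, n_samples)
    storage.mode(counts) <- "integer"
    rownames(counts) <- sprintf("gene_%04d", seq_len(g))
    colnames(counts) <- sample_ids
    list(counts = counts,
         samples = data.frame(sample = sample_ids, group = group_of,
                              stringsAsFactors = FALSE),
         genes = data.frame(gene = rownames(counts), module = module,
                            stringsAsFactors = FALSE))
  })
}

# Eclosion survival probabilities per genotype, with the larval sample sizes
# reported for each condition (48 is the stand-in where none was printed).
.eclosion_presets <- list(
  FRT19A       = list(p_eclose = 0.99, n_larvae = 163L),
  ph505        = list(p_eclose = 0.12, n_larvae = 784L),
  ph505_rescue = list(p_eclose = 0.97, n_larvae = 48L),
  ph505_ato    = list(p_eclose = 0.84, n_larvae = 95L),
  ph505_kniKD2 = list(p_eclose = 0.85, n_larvae = 48L),
  kni_ectopic  = list(p_eclose = 0.35, n_larvae = 441L),
  ph505_dome   = list(p_eclose = 0.85, n_larvae = 48L))

#' Eclosion-simulation parameters
#'
#' @param genotype genotype label.
#' @param n_larvae number of GFP-selected larvae transferred (>= 1).
#' @param p_eclose probability that a larva ecloses as an adult, in `[0, 1]`.
#' @return Object of class `eclosion_sim_params`.
#' @export
eclosion_sim_params <- function(genotype, n_larvae, p_eclose) {
  n_larvae <- as.integer(n_larvae)
  if (is.na(n_larvae) || n_larvae < 1L) {
    stop("`n_larvae` must be >= 1", call. = FALSE)
  }
  if (!is.finite(p_eclose) || p_eclose < 0 || p_eclose > 1) {
    stop("`p_eclose` must be in [0, 1]", call. = FALSE)
  }
  structure(list(genotype = as.character(genotype), n_larvae = n_larvae,
                 p_eclose = p_eclose),
            class = "eclosion_sim_params")
}

#' Eclosion preset for a named genotype
#'
#' Survival probabilities follow the reported rates: FRT19A control 99%,
#' ph505 12%, UAS-ph rescue 97%, atonal overexpression 84%, second kni RNAi
#' line 85%, ectopic kni in neutral clones 35%, JAK/STAT block 85%.
#'
#' @param name one of `r paste(names(.eclosion_presets), collapse = ", ")`.
#' @param n_larvae optional override of the larval count.
#' @return An `eclosion_sim_params` object.
#' @export
make_eclosion_preset <- function(name, n_larvae = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.eclosion_presets)) {
    stop(sprintf("unknown eclosion preset '%s'; valid presets: %s",
                 as.character(name)[1],
                 paste(names(.eclosion_presets), collapse = ", ")),
         call. = FALSE)
  }
  p <- .eclosion_presets[[name]]
  eclosion_sim_params(name, n_larvae %||% p$n_larvae, p$p_eclose)
}

#' Simulate one eclosion experiment
#'
#' Adults eclosing from `n_larvae` selected larvae are binomial with the
#' genotype's survival probability.
#'
#' @param params an [eclosion_sim_params()] object.
#' @param seed integer seed.
#' @return Data frame row with `genotype`, `n_larvae`, `n_adults`.
#' @examples
#' simulate_eclosion(make_eclosion_preset("ph505_rescue"), seed = 1)
#' @export
simulate_eclosion <- function(params, seed) {
  if (!inherits(params, "eclosion_sim_params")) {
    stop("`params` must be an eclosion_sim_params object", call. = FALSE)
  }
  with_seed(seed, {
    data.frame(genotype = params$genotype, n_larvae = params$n_larvae,
               n_adults = stats::rbinom(1, params$n_larvae, params$p_eclose),
               stringsAsFactors = FALSE)
  })
}
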