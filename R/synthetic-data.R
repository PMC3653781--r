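# Seeded generative model for a two-source cell-free seminal DNA (cfsDNA)
# MeDIP promoter-array study with planted, recoverable truth.
#
# The model emulates the study design: one pooled hybridization per condition
# ("Nor" = normozoospermic donors, "PV" = post-vasectomy men). Nor cfsDNA is a
# mixture in which a fraction (default 0.73) derives from testis/epididymis
# (TE); PV cfsDNA contains no TE-derived DNA, so contrasting the two isolates
# the TE contribution.

#' Simulation settings for the synthetic promoter array
#'
#' Describes a NimbleGen-style promoter tiling design: one promoter window
#' per accession spanning `promoter_upstream` bp upstream to
#' `promoter_downstream` bp downstream of the TSS in transcription
#' orientation, tiled by probes every `probe_spacing` bp, together with the
#' proportions of planted differential promoters.
#'
#' Planted classes: "TE-specific hypomethylated" promoters are unmethylated
#' in the testis/epididymis source and methylated in the accessory-gland
#' background; "TE-specific hypermethylated" promoters are the reverse.
#' Non-differential promoters are either methylated in both sources
#' (`fraction_background_methylated`) or unmethylated in both (the rest).
#' `fraction_background_methylated` defaults to 0.096 so that the expected
#' fraction of promoters carrying a methylation peak in at least one
#' condition is about 22.8%, the rate observed on the real array
#' (4111/18028 promoters).
#'
#' @param n_genes Number of promoters (one accession per gene) to simulate.
#' @param promoter_upstream,promoter_downstream Promoter window extent in bp
#'   around the TSS (defaults 2200 and 500).
#' @param probe_spacing Distance between consecutive probe starts in bp.
#' @param probe_length Probe footprint in bp.
#' @param fraction_te_hypo,fraction_te_hyper Proportions of promoters planted
#'   as TE-specific hypo-/hypermethylated (defaults 0.0971 and 0.0353).
#' @param fraction_background_methylated Proportion of promoters methylated
#'   in both sources (non-differential but peak-bearing).
#' @param genes_per_chrom Promoters placed per synthetic chromosome
#'   ("chrS1", "chrS2", ...).
#' @param intergenic_gap Gap in bp between consecutive promoter windows on a
#'   chromosome; kept >= 5000 so windows never overlap or share probes.
#' @param seed Integer seed; all generator operations are pure functions of
#'   the configuration and this seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes,
                              promoter_upstream = 2200,
                              promoter_downstream = 500,
                              probe_spacing = 100,
                              probe_length = 50,
                              fraction_te_hypo = 0.0971,
                              fraction_te_hyper = 0.0353,
                              fraction_background_methylated = 0.096,
                              genes_per_chrom = 100,
                              intergenic_gap = 8000,
                              seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(promoter_upstream, "promoter_upstream", lower = 0)
  assert_scalar_number(promoter_downstream, "promoter_downstream", lower = 0)
  assert_scalar_number(probe_spacing, "probe_spacing", lower = 1)
  assert_scalar_number(probe_length, "probe_length", lower = 1)
  assert_scalar_number(fraction_te_hypo, "fraction_te_hypo", 0, 1)
  assert_scalar_number(fraction_te_hyper, "fraction_te_hyper", 0, 1)
  assert_scalar_number(fraction_background_methylated,
                       "fraction_background_methylated", 0, 1)
  if (fraction_te_hypo + fraction_te_hyper >= 1) {
    stop("fraction_te_hypo + fraction_te_hyper must be < 1", call. = FALSE)
  }
  if (fraction_te_hypo + fraction_te_hyper + fraction_background_methylated > 1) {
    stop("planted class fractions sum to more than 1", call. = FALSE)
  }
  window <- promoter_upstream + promoter_downstream
  if (probe_spacing >= window) {
    stop("probe_spacing must be smaller than the promoter window", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    probe_spacing = as.integer(probe_spacing),
    probe_length = as.integer(probe_length),
    fraction_te_hypo = fraction_te_hypo,
    fraction_te_hyper = fraction_te_hyper,
    fraction_background_methylated = fraction_background_methylated,
    genes_per_chrom = as.integer(genes_per_chrom),
    intergenic_gap = as.integer(intergenic_gap),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Two-source mixture model for cfsDNA probe signal
#'
#' Let `f` be the testis/epididymis fraction of a condition's cfsDNA
#' (`fraction_te` for Nor, `fraction_te_pv` for PV) and `mu(state)` be
#' `mu_methylated` or `mu_unmethylated`. Under the default
#' `signal_model = "component"`, each probe's scaled log2(IP/Input) value is
#' drawn from the TE component `Normal(mu(state_te), sigma_probe)` with
#' probability `f` and from the background component
#' `Normal(mu(state_bg), sigma_probe)` otherwise: a promoter that is
#' methylated in only one source shows probe-level heterogeneity, the way
#' partial methylation presents on enrichment arrays, while the expected
#' probe mean keeps the closed form
#' `f * mu(state_te) + (1 - f) * mu(state_bg)`. With
#' `signal_model = "mean"`, every probe is drawn from
#' `Normal(f * mu(state_te) + (1 - f) * mu(state_bg), sigma_probe)`; that
#' variant turns partial methylation into a uniform intermediate shift over
#' the whole promoter, which a rank-based peak caller detects as a
#' (spurious) coherent peak, so it is kept only for studying that failure
#' mode. At `f` of 0 or 1 the two models coincide.
#'
#' @param fraction_te Proportion of Nor cfsDNA derived from
#'   testis/epididymis; default 0.73, the value implied by the cohort
#'   concentration contrast (Nor about quadruple of PV).
#' @param fraction_te_pv TE fraction for PV cfsDNA; 0 after a successful
#'   vasectomy.
#' @param mu_methylated,mu_unmethylated Mean probe log-ratio for a fully
#'   methylated / unmethylated locus in a pure source.
#' @param sigma_probe Per-probe Gaussian noise SD on the log-ratio scale.
#' @param signal_model "component" (default) or "mean"; see Details.
#' @param seed Integer seed for the array draw.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(fraction_te = 0.73,
                          fraction_te_pv = 0,
                          mu_methylated = 1.5,
                          mu_unmethylated = 0,
                          sigma_probe = 0.4,
                          signal_model = c("component", "mean"),
                          seed = 1L) {
  signal_model <- match.arg(signal_model)
  assert_scalar_number(fraction_te, "fraction_te", 0, 1)
  assert_scalar_number(fraction_te_pv, "fraction_te_pv", 0, 1)
  assert_scalar_number(mu_methylated, "mu_methylated")
  assert_scalar_number(mu_unmethylated, "mu_unmethylated")
  if (mu_methylated <= mu_unmethylated) {
    stop("mu_methylated must exceed mu_unmethylated", call. = FALSE)
  }
  assert_scalar_number(sigma_probe, "sigma_probe", lower = 0,
                       strict_lower = TRUE)
  structure(list(
    fraction_te = fraction_te,
    fraction_te_pv = fraction_te_pv,
    mu_methylated = mu_methylated,
    mu_unmethylated = mu_unmethylated,
    sigma_probe = sigma_probe,
    signal_model = signal_model,
    seed = as.integer(seed)
  ), class = "mixture_model")
}

#' Generate a synthetic promoter annotation
#'
#' Places `n_genes` promoters on synthetic chromosomes ("chrS1", ...) with
#' non-overlapping windows separated by `intergenic_gap` bp. Strand is drawn
#' at random under the configuration seed; the promoter interval is oriented
#' by strand: `[tss - upstream, tss + downstream)` on "+",
#' `[tss - downstream, tss + upstream)` on "-" (0-based half-open).
#'
#' @param config A [simulation_config()].
#' @return A promoter annotation data frame with columns `gene_symbol`,
#'   `accession`, `chrom`, `tss`, `strand`, `start`, `end`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  win <- config$promoter_upstream + config$promoter_downstream
  idx <- seq_len(n)
  chrom_idx <- (idx - 1L) %/% config$genes_per_chrom + 1L
  slot_idx <- (idx - 1L) %% config$genes_per_chrom
  slot_start <- 10000L + slot_idx * (win + config$intergenic_gap)
  strand <- withr::with_seed(config$seed + 1L,
                             sample(c("+", "-"), n, replace = TRUE))
  tss <- ifelse(strand == "+",
                slot_start + config$promoter_upstream,
                slot_start + config$promoter_downstream)
  data.frame(
    gene_symbol = sprintf("GENE%05d", idx),
    accession = sprintf("NMS%06d", idx),
    chrom = paste0("chrS", chrom_idx),
    tss = as.integer(tss),
    strand = strand,
    start = as.integer(slot_start),
    end = as.integer(slot_start + win),
    stringsAsFactors = FALSE
  )
}

#' Plant per-promoter tissue methylation states
#'
#' Assigns each promoter a methylation state in the testis/epididymis (TE)
#' source and in the accessory-gland background source. Class counts equal
#' `round(n_genes * fraction)` for the TE-specific hypo-/hypermethylated
#' classes and for the both-methylated background class; assignment to
#' promoters is a seeded permutation.
#'
#' @param annotation Output of [generate_annotation()].
#' @param config The [simulation_config()] used to build `annotation`.
#' @return A truth data frame with columns `gene_symbol`, `accession`,
#'   `state_te`, `state_bg` (each "methylated"/"unmethylated") and `class`
#'   ("te_hypomethylated", "te_hypermethylated" or "none").
#' @export
plant_truth <- function(annotation, config) {
  stopifnot(inherits(config, "simulation_config"))
  assert_columns(annotation, c("gene_symbol", "accession"), "annotation")
  n <- nrow(annotation)
  n_hypo <- round(n * config$fraction_te_hypo)
  n_hyper <- round(n * config$fraction_te_hyper)
  n_bgme <- round(n * config$fraction_background_methylated)
  if (n_hypo + n_hyper + n_bgme > n) {
    stop("planted class counts exceed the number of promoters", call. = FALSE)
  }
  ord <- withr::with_seed(config$seed + 2L, sample.int(n))
  klass <- rep("none", n)
  state_te <- rep("unmethylated", n)
  state_bg <- rep("unmethylated", n)
  hypo_idx <- ord[seq_len(n_hypo)]
  hyper_idx <- ord[seq_len(n_hyper) + n_hypo]
  bgme_idx <- ord[seq_len(n_bgme) + n_hypo + n_hyper]
  klass[hypo_idx] <- "te_hypomethylated"
  state_te[hypo_idx] <- "unmethylated"
  state_bg[hypo_idx] <- "methylated"
  klass[hyper_idx] <- "te_hypermethylated"
  state_te[hyper_idx] <- "methylated"
  state_bg[hyper_idx] <- "unmethylated"
  state_te[bgme_idx] <- "methylated"
  state_bg[bgme_idx] <- "methylated"
  data.frame(
    gene_symbol = annotation$gene_symbol,
    accession = annotation$accession,
    state_te = state_te,
    state_bg = state_bg,
    class = klass,
    stringsAsFactors = FALSE
  )
}

state_mean <- function(state, mixture) {
  ifelse(state == "methylated", mixture$mu_methylated, mixture$mu_unmethylated)
}

#' Simulate the two pooled array profiles
#'
#' Tiles every promoter with probes at `probe_spacing` and draws each probe's
#' scaled log2(IP/Input) value from the two-source mixture model (see
#' [mixture_model()] for the signal models): the Nor pool mixes the TE and
#' background sources at `f = fraction_te`; the PV pool uses
#' `f = fraction_te_pv` (0 by default, so PV reflects the background source
#' alone). In either model the expected probe mean is
#' `f * mu(state_te) + (1 - f) * mu(state_bg)`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [plant_truth()] on the same annotation.
#' @param mixture A [mixture_model()].
#' @param config The [simulation_config()] (probe geometry).
#' @return A list with elements `nor` and `pv`, each an `array_profile`
#'   data frame (`probe_id`, `chrom`, `start`, `end`, `value`) sorted by
#'   (chrom, start), with the condition label stored as an attribute.
#' @export
simulate_arrays <- function(annotation, truth, mixture, config) {
  stopifnot(inherits(mixture, "mixture_model"),
            inherits(config, "simulation_config"))
  if (nrow(annotation) == 0L) {
    stop("annotation is empty; nothing to simulate", call. = FALSE)
  }
  truth <- truth[match(annotation$accession, truth$accession), , drop = FALSE]
  if (anyNA(truth$state_te)) {
    stop("truth does not cover every annotated accession", call. = FALSE)
  }
  starts_by_gene <- lapply(seq_len(nrow(annotation)), function(i) {
    seq.int(annotation$start[i], annotation$end[i] - config$probe_length,
            by = config$probe_spacing)
  })
  gene_idx <- rep.int(seq_len(nrow(annotation)),
                      lengths(starts_by_gene))
  start <- unlist(starts_by_gene, use.names = FALSE)
  probes <- data.frame(
    chrom = annotation$chrom[gene_idx],
    start = as.integer(start),
    end = as.integer(start + config$probe_length),
    gene_idx = gene_idx,
    stringsAsFactors = FALSE
  )
  np <- nrow(probes)
  mu_te <- state_mean(truth$state_te, mixture)[probes$gene_idx]
  mu_bg <- state_mean(truth$state_bg, mixture)[probes$gene_idx]
  draw <- function(f) {
    mu <- if (mixture$signal_model == "component") {
      ifelse(stats::runif(np) < f, mu_te, mu_bg)
    } else {
      f * mu_te + (1 - f) * mu_bg
    }
    stats::rnorm(np, mu, mixture$sigma_probe)
  }
  vals <- withr::with_seed(mixture$seed + 3L, {
    list(nor = draw(mixture$fraction_te),
         pv = draw(mixture$fraction_te_pv))
  })
  ord <- order(probes$chrom, probes$start)
  build <- function(v, label) {
    df <- data.frame(
      probe_id = sprintf("P%07d", seq_len(np)),
      chrom = probes$chrom[ord],
      start = probes$start[ord],
      end = probes$end[ord],
      value = v[ord],
      stringsAsFactors = FALSE
    )
    as_array_profile(df, label)
  }
  list(nor = build(vals$nor, "Nor"), pv = build(vals$pv, "PV"))
}

#' Assay parameters for simulated Ct tables
#'
#' PCR efficiency is fixed at 2 (perfect doubling per cycle), matching the
#' quantification formulas.
#'
#' @param baseline_ct Quantification-cycle baseline for reference reactions.
#' @param dilution_factor Dilution factor of the Input DNA for MeDIP-qPCR.
#' @param noise_sd Gaussian noise SD added to every simulated Ct.
#' @param fullmeth_delta_ct Target-minus-reference Ct difference of the fully
#'   methylated control DNA in MethyLight.
#' @param unmeth_extra_ct Extra cycles of the methylation-specific reaction
#'   on unmethylated control DNA beyond the fully methylated control (the
#'   assay's specificity margin; > 5 cycles in a specific assay).
#' @param seed Integer seed.
#' @return An object of class `assay_params`.
#' @export
assay_params <- function(baseline_ct = 28,
                         dilution_factor = 1,
                         noise_sd = 0,
                         fullmeth_delta_ct = 0.5,
                         unmeth_extra_ct = 9,
                         seed = 1L) {
  assert_scalar_number(baseline_ct, "baseline_ct", 0, 45,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(dilution_factor, "dilution_factor", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(fullmeth_delta_ct, "fullmeth_delta_ct")
  assert_scalar_number(unmeth_extra_ct, "unmeth_extra_ct", lower = 0)
  structure(list(
    baseline_ct = baseline_ct,
    dilution_factor = dilution_factor,
    noise_sd = noise_sd,
    fullmeth_delta_ct = fullmeth_delta_ct,
    unmeth_extra_ct = unmeth_extra_ct,
    seed = as.integer(seed)
  ), class = "assay_params")
}

#' Simulate MeDIP-qPCR and MethyLight Ct tables
#'
#' Inverts the quantification formulas so that, at zero noise, the
#' calculators recover the planted values exactly:
#' `Ct(IP) - Ct(Input) = -log2(enrichment / dilution_factor)` for MeDIP-qPCR
#' (so `2^-dCt * dilution * 100` returns `100 * enrichment`), and
#' `ddCt = -log2(methylation)` for MethyLight. A planted methylation of 0
#' cannot produce a finite Ct; such loci are emitted with `censored = TRUE`
#' and a missing sample Ct.
#'
#' @param loci Data frame with columns `locus_id`, `enrichment` (true
#'   IP/Input fraction, > 0) and `methylation` (true methylated fraction in
#'   \[0, 1\]).
#' @param assay An [assay_params()].
#' @return A list with data frames `qpcr` (`locus_id`, `ct_ip`, `ct_input`,
#'   `dilution_factor`) and `methylight` (`locus_id`, `ct_target_sample`,
#'   `ct_reference_sample`, `ct_target_fullmeth`, `ct_reference_fullmeth`,
#'   `ct_target_unmeth`, `censored`).
#' @export
simulate_ct_tables <- function(loci, assay = assay_params()) {
  stopifnot(inherits(assay, "assay_params"))
  assert_columns(loci, c("locus_id", "enrichment", "methylation"), "loci")
  if (any(!is.finite(loci$enrichment)) || any(loci$enrichment <= 0)) {
    stop("true enrichment must be positive for every locus", call. = FALSE)
  }
  if (any(!is.finite(loci$methylation)) ||
      any(loci$methylation < 0 | loci$methylation > 1)) {
    stop("true methylation must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(loci)
  withr::with_seed(assay$seed + 4L, {
    noise <- function() stats::rnorm(n, 0, assay$noise_sd)
    ct_input <- assay$baseline_ct + noise()
    ct_ip <- ct_input + log2(assay$dilution_factor / loci$enrichment) + noise()
    qpcr <- data.frame(
      locus_id = loci$locus_id,
      ct_ip = ct_ip,
      ct_input = ct_input,
      dilution_factor = assay$dilution_factor,
      stringsAsFactors = FALSE
    )
    censored <- loci$methylation == 0
    ct_ref_sample <- assay$baseline_ct + noise()
    ct_ref_full <- assay$baseline_ct + noise()
    ct_tgt_full <- ct_ref_full + assay$fullmeth_delta_ct + noise()
    ct_tgt_sample <- ct_ref_sample + assay$fullmeth_delta_ct -
      log2(loci$methylation) + noise()
    ct_tgt_sample[censored] <- NA_real_
    methylight <- data.frame(
      locus_id = loci$locus_id,
      ct_target_sample = ct_tgt_sample,
      ct_reference_sample = ct_ref_sample,
      ct_target_fullmeth = ct_tgt_full,
      ct_reference_fullmeth = ct_ref_full,
      ct_target_unmeth = ct_tgt_full + assay$unmeth_extra_ct + noise(),
      censored = censored,
      stringsAsFactors = FALSE
    )
    list(qpcr = qpcr, methylight = methylight)
  })
}

#' Simulate a cohort of cfsDNA concentrations
#'
#' Draws per-subject seminal-plasma cfsDNA concentrations (ug/ml) for the Nor
#' and PV groups from Gaussians at the study's group means and SDs,
#' truncated to positive values by redrawing.
#'
#' @param n_nor,n_pv Group sizes (study: 12 and 11).
#' @param mean_nor,sd_nor Nor group mean and SD (study: 1.23 +/- 0.32).
#' @param mean_pv,sd_pv PV group mean and SD (study: 0.33 +/- 0.09).
#' @param seed Integer seed.
#' @return Data frame with columns `group` ("Nor"/"PV"), `subject_id`,
#'   `concentration`.
#' @export
simulate_cohort <- function(n_nor = 12, n_pv = 11,
                            mean_nor = 1.23, sd_nor = 0.32,
                            mean_pv = 0.33, sd_pv = 0.09,
                            seed = 1L) {
  draw_pos <- function(n, mu, sd) {
    x <- stats::rnorm(n, mu, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sd)
    x
  }
  withr::with_seed(as.integer(seed) + 5L, {
    data.frame(
      group = c(rep("Nor", n_nor), rep("PV", n_pv)),
      subject_id = c(sprintf("NOR%02d", seq_len(n_nor)),
                     sprintf("PV%02d", seq_len(n_pv))),
      concentration = c(draw_pos(n_nor, mean_nor, sd_nor),
                        draw_pos(n_pv, mean_pv, sd_pv)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a gene-to-category map with one planted enriched category
#'
#' Builds random functional categories over the simulated gene universe plus
#' one planted category that oversamples the TE-specific hypomethylated
#' genes, emulating a reproduction-related term that a category enrichment
#' analysis should rank first.
#'
#' @param truth Output of [plant_truth()].
#' @param n_categories Number of random categories.
#' @param category_size Genes per category.
#' @param planted_category Name of the planted category.
#' @param planted_fraction Fraction of the planted category drawn from the
#'   TE-specific hypomethylated genes.
#' @param seed Integer seed.
#' @return A list with `categories` (named list of gene vectors) and
#'   `universe` (all simulated gene symbols).
#' @export
simulate_category_map <- function(truth, n_categories = 20,
                                  category_size = 40,
                                  planted_category = "SEXUAL_REPRODUCTION_LIKE",
                                  planted_fraction = 0.6,
                                  seed = 1L) {
  universe <- unique(truth$gene_symbol)
  hypo <- truth$gene_symbol[truth$class == "te_hypomethylated"]
  category_size <- min(category_size, length(universe))
  withr::with_seed(as.integer(seed) + 6L, {
    cats <- lapply(seq_len(n_categories), function(i) {
      sample(universe, category_size)
    })
    names(cats) <- sprintf("CAT%03d", seq_len(n_categories))
    n_planted <- min(length(hypo), round(planted_fraction * category_size))
    planted <- c(sample(hypo, n_planted),
                 sample(setdiff(universe, hypo), category_size - n_planted))
    cats[[planted_category]] <- planted
    list(categories = cats, universe = universe)
  })
}
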