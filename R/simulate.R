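#' @keywords internal
#' Run an expression under a fixed RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Default mapping from maternal lineage to mitochondrial haplotype label
#'
#' Mitotypes are maternally inherited, so within the simulator they are a
#' deterministic function of the colony's maternal lineage. Lineage C maps
#' to the C1 mitotype common in \emph{A. m. ligustica} apiaries.
#'
#' @export
DEFAULT_MITOTYPE_MAP <- c(A = "A", C = "C1", M = "M", O = "O")

#' Sequencing-simulation configuration
#'
#' Depth tiers reflect the strong matrix-quality gradient of honey eDNA
#' assays: DNA taken directly from bees (larvae, worker pools) sequences
#' one to two orders of magnitude deeper than DNA recovered from honey,
#' and bulk honey (pooled from several colonies, often stored) is the
#' most degraded. Defaults are mean per-marker depths of roughly 26,450x
#' (larva), 17,480x (worker pool), 5,560x (honeycomb honey) and 1,140x
#' (bulk honey), with negative-binomial dispersion `size = 2` to mimic the
#' very high between-sample depth variability of multiplexed amplicon runs.
#'
#' Marker dropout is logistic in log depth,
#' `P(missing) = plogis(intercept - slope * log(DP) + offsets)`, with an
#' additive offset for honey-derived matrices (degraded template) and a
#' further offset for a small set of "fragile" markers whose amplicons
#' underperform in degraded DNA — reproducing the observation that a
#' handful of specific markers fall below a 90 percent call rate in honey
#' while bee-derived samples genotype completely.
#'
#' @param depth_tier_mean Named numeric, expected per-marker depth by
#'   matrix type.
#' @param depth_dispersion Negative-binomial `size`; smaller = noisier.
#' @param base_error_rate Per-read allele error rate folded into the
#'   binomial success probability as `f(1-e) + (1-f)e`.
#' @param fragile_marker_ids Marker ids with inflated dropout.
#' @param dropout_intercept,dropout_slope Logistic dropout parameters
#'   versus `log(DP)`.
#' @param honey_dropout_offset,fragile_dropout_offset Additive logit
#'   offsets for honey matrices and fragile markers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(depth_tier_mean = c(larva = 26450, worker_pool = 17480,
                                           honeycomb_honey = 5560,
                                           bulk_honey = 1140),
                       depth_dispersion = 2,
                       base_error_rate = 0.005,
                       fragile_marker_ids = c("bee_snp_42", "bee_snp_78",
                                              "bee_snp_79", "bee_snp_93",
                                              "bee_calm_3", "Var_res_21"),
                       dropout_intercept = -2,
                       dropout_slope = 1,
                       honey_dropout_offset = 3.5,
                       fragile_dropout_offset = 4.5) {
  stopifnot(all(depth_tier_mean > 0), depth_dispersion > 0,
            base_error_rate >= 0, base_error_rate <= 1)
  structure(list(depth_tier_mean = depth_tier_mean,
                 depth_dispersion = depth_dispersion,
                 base_error_rate = base_error_rate,
                 fragile_marker_ids = fragile_marker_ids,
                 dropout_intercept = dropout_intercept,
                 dropout_slope = dropout_slope,
                 honey_dropout_offset = honey_dropout_offset,
                 fragile_dropout_offset = fragile_dropout_offset),
            class = "sim_config")
}

#' Draw lineage-differentiated allele-frequency profiles
#'
#' Generates the population structure the ancestry panel is designed to
#' detect: an ancestral allele frequency per marker, and per-lineage
#' frequencies drawn from the Balding-Nichols model
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral `p` and
#' whose variance `p(1-p)F` grows with the divergence parameter `F`.
#'
#' @param panel A `bee_panel`; profiles cover every marker.
#' @param lineages Character vector of lineage labels.
#' @param F Divergence in (0, 1); scalar or one value per lineage.
#' @param seed Integer seed (all simulator randomness is seed-explicit).
#' @return A `lineage_profiles` list: `lineages`, `markers`,
#'   `ancestral_freq` (per marker), `lineage_freq` (lineage x marker
#'   matrix), `F` (named per lineage).
#' @export
make_lineage_profiles <- function(panel, lineages = c("A", "C", "M", "O"),
                                  F = 0.2, seed = 1L) {
  stopifnot(inherits(panel, "bee_panel"), length(lineages) >= 1L)
  if (any(F <= 0) || any(F >= 1)) stop("divergence F must lie in (0, 1)")
  F <- rep_len(F, length(lineages))
  names(F) <- lineages
  m <- nrow(panel)
  with_seed(seed, {
    p <- stats::runif(m, 0.05, 0.95)
    lf <- matrix(NA_real_, nrow = length(lineages), ncol = m,
                 dimnames = list(lineages, panel$marker_id))
    for (lin in lineages) {
      a <- p * (1 - F[[lin]]) / F[[lin]]
      b <- (1 - p) * (1 - F[[lin]]) / F[[lin]]
      lf[lin, ] <- stats::rbeta(m, a, b)
    }
    structure(list(lineages = lineages,
                   markers = panel$marker_id,
                   ancestral_freq = stats::setNames(p, panel$marker_id),
                   lineage_freq = lf, F = F),
              class = "lineage_profiles")
  })
}

#' Found a haplodiploid colony
#'
#' A colony is one diploid queen mated to several haploid drones; every
#' worker inherits one uniformly chosen queen allele and the allele of one
#' uniformly chosen drone father. The colony's true allele frequency —
#' the quantity honey eDNA sequencing estimates — is the mean worker
#' alternative-allele dosage divided by 2, recomputed from the realised
#' workers rather than from expectations.
#'
#' @param profiles A `lineage_profiles`.
#' @param maternal Queen's lineage label.
#' @param paternal Lineage of the "foreign" drone fathers; with
#'   `alpha = 0` all drones are maternal-lineage.
#' @param alpha Fraction of drone fathers drawn from `paternal` (admixture
#'   of the colony's paternal gene pool).
#' @param n_drones Number of drone fathers (queens are polyandrous;
#'   default 12 matings).
#' @param n_workers Workers realised in the colony; thousands of workers
#'   contribute DNA traces to honey (default 1000), a sequenced pool uses
#'   35, a single larva 1.
#' @param seed Integer seed.
#' @param colony_id Identifier.
#' @param mitotype_map Named map lineage -> mitotype label.
#' @return A `colony_model` list including `queen_genotype` (dosage 0/1/2
#'   per marker), `drone_haplotypes` (drones x markers 0/1),
#'   `worker_dosage` (workers x markers 0/1/2), `true_colony_af` in
#'   [0, 1], and the maternally inherited `mitotype`.
#' @export
found_colony <- function(profiles, maternal, paternal = maternal, alpha = 0,
                         n_drones = 12L, n_workers = 1000L, seed = 1L,
                         colony_id = "colony_1",
                         mitotype_map = DEFAULT_MITOTYPE_MAP) {
  stopifnot(inherits(profiles, "lineage_profiles"),
            n_drones >= 1L, n_workers >= 1L, alpha >= 0, alpha <= 1)
  for (lin in unique(c(maternal, paternal))) {
    if (!lin %in% profiles$lineages) stop("unknown lineage label: ", lin)
  }
  m <- length(profiles$markers)
  p_mat <- profiles$lineage_freq[maternal, ]
  p_pat <- profiles$lineage_freq[paternal, ]
  with_seed(seed, {
    queen_a1 <- stats::rbinom(m, 1L, p_mat)
    queen_a2 <- stats::rbinom(m, 1L, p_mat)
    drone_from_pat <- stats::rbinom(n_drones, 1L, alpha) == 1L
    drone_hap <- matrix(0L, nrow = n_drones, ncol = m,
                        dimnames = list(NULL, profiles$markers))
    for (d in seq_len(n_drones)) {
      drone_hap[d, ] <- stats::rbinom(m, 1L, if (drone_from_pat[d]) p_pat else p_mat)
    }
    pick_q <- matrix(stats::runif(n_workers * m) < 0.5, n_workers, m)
    queen_allele <- matrix(rep(queen_a1, each = n_workers), n_workers, m)
    queen_allele[!pick_q] <- matrix(rep(queen_a2, each = n_workers),
                                    n_workers, m)[!pick_q]
    father <- sample.int(n_drones, n_workers, replace = TRUE)
    worker_dosage <- queen_allele + drone_hap[father, , drop = FALSE]
    colnames(worker_dosage) <- profiles$markers
    true_af <- colMeans(worker_dosage) / 2
    if (!maternal %in% names(mitotype_map)) {
      stop("no mitotype mapped for lineage ", maternal)
    }
    structure(list(colony_id = colony_id,
                   maternal_lineage = maternal,
                   paternal_lineage = paternal,
                   admixture_alpha = alpha,
                   queen_genotype = stats::setNames(queen_a1 + queen_a2,
                                                    profiles$markers),
                   drone_haplotypes = drone_hap,
                   n_workers = as.integer(n_workers),
                   worker_dosage = worker_dosage,
                   true_colony_af = true_af,
                   mitotype = unname(mitotype_map[[maternal]])),
              class = "colony_model")
  })
}

#' Simulate one sample's amplicon read counts from a colony
#'
#' Per marker, total depth DP is negative-binomial around the matrix
#' type's tier mean; the marker drops out (missing) with the logistic
#' dropout probability in log DP (see [sim_config()]); otherwise ALT reads
#' are binomial with success probability `f(1-e) + (1-f)e` where `f` is
#' the colony's true allele frequency and `e` the base error rate.
#'
#' @param colony A `colony_model`.
#' @param matrix_type One of the sequenced matrix types with a configured
#'   depth tier.
#' @param cfg A `sim_config`.
#' @param seed Integer seed.
#' @return A depth row: list of named integer vectors `ref` and `alt`
#'   (`NA` = dropped marker), suitable for [bind_count_rows()] and
#'   [write_sample_vcf()].
#' @export
simulate_counts <- function(colony, matrix_type, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(colony, "colony_model"), inherits(cfg, "sim_config"))
  if (!matrix_type %in% names(cfg$depth_tier_mean)) {
    stop("no depth tier configured for matrix type: ", matrix_type)
  }
  f <- colony$true_colony_af
  m <- length(f)
  markers <- names(f)
  eps <- cfg$base_error_rate
  q <- f * (1 - eps) + (1 - f) * eps
  with_seed(seed, {
    dp <- stats::rnbinom(m, size = cfg$depth_dispersion,
                         mu = cfg$depth_tier_mean[[matrix_type]])
    lp <- cfg$dropout_intercept - cfg$dropout_slope * log(pmax(dp, 1L))
    if (matrix_type %in% HONEY_MATRIX_TYPES) lp <- lp + cfg$honey_dropout_offset
    lp[markers %in% cfg$fragile_marker_ids] <-
      lp[markers %in% cfg$fragile_marker_ids] + cfg$fragile_dropout_offset
    dropped <- dp == 0L | stats::runif(m) < stats::plogis(lp)
    alt <- stats::rbinom(m, dp, q)
    ref <- dp - alt
    ref[dropped] <- NA_integer_
    alt[dropped] <- NA_integer_
    list(ref = stats::setNames(as.integer(ref), markers),
         alt = stats::setNames(as.integer(alt), markers))
  })
}

#' Simulate two independent aliquots of the same sample
#'
#' Models the duplicate-aliquot concordance experiment: DNA extracted twice
#' from one source, sequenced independently. Both rows are drawn from the
#' same colony truth; they differ only through sequencing noise and
#' dropout.
#'
#' @param colony A `colony_model`.
#' @param matrix_type Sequenced matrix type.
#' @param cfg A `sim_config`.
#' @param seed_a,seed_b Distinct seeds for the two aliquots.
#' @return List of two depth rows `a` and `b`.
#' @export
simulate_duplicate <- function(colony, matrix_type, cfg = sim_config(),
                               seed_a = 1L, seed_b = 2L) {
  if (identical(as.integer(seed_a), as.integer(seed_b))) {
    stop("aliquot seeds must differ")
  }
  list(a = simulate_counts(colony, matrix_type, cfg, seed = seed_a),
       b = simulate_counts(colony, matrix_type, cfg, seed = seed_b))
}

#' Simulate an individual-genotype reference panel
#'
#' Reference sets (previously genotyped bees, WGS datasets) enter the
#' ancestry analysis as individual diploid genotypes encoded as
#' alternative-allele frequency 0/50/100. Each individual draws two
#' Bernoulli alleles from its lineage's frequency at every marker.
#'
#' @param profiles A `lineage_profiles`.
#' @param n_per_lineage Named integer vector; names are lineage labels and
#'   may repeat (e.g. two subspecies of the same lineage).
#' @param seed Integer seed.
#' @param matrix_type `"genotype_reference"` or `"wgs_reference"`.
#' @param id_prefix Sample-id prefix.
#' @param markers Optional marker subset (default: all profile markers).
#' @return List with `af` (rows x markers matrix of 0/50/100, provenance
#'   `genotype_derived`) and `sheet` (a `sample_sheet`).
#' @export
simulate_reference_panel <- function(profiles, n_per_lineage, seed = 1L,
                                     matrix_type = "genotype_reference",
                                     id_prefix = "ref",
                                     markers = NULL) {
  stopifnot(inherits(profiles, "lineage_profiles"),
            all(n_per_lineage >= 1L), !is.null(names(n_per_lineage)),
            matrix_type %in% REFERENCE_MATRIX_TYPES)
  if (is.null(markers)) markers <- profiles$markers
  bad <- setdiff(names(n_per_lineage), profiles$lineages)
  if (length(bad) > 0L) stop("unknown lineage label: ", paste(bad, collapse = ", "))
  n_total <- sum(n_per_lineage)
  m <- length(markers)
  with_seed(seed, {
    lin_of_row <- rep(names(n_per_lineage), times = n_per_lineage)
    geno <- matrix(NA_real_, nrow = n_total, ncol = m,
                   dimnames = list(paste0(id_prefix, "_", seq_len(n_total)),
                                   markers))
    for (i in seq_len(n_total)) {
      p <- profiles$lineage_freq[lin_of_row[i], markers]
      geno[i, ] <- 50 * (stats::rbinom(m, 1L, p) + stats::rbinom(m, 1L, p))
    }
    sheet <- sample_sheet(data.frame(
      sample_id = rownames(geno),
      matrix_type = matrix_type,
      subspecies = NA_character_,
      lineage = lin_of_row,
      duplicate_group = NA_character_,
      n_individuals = 1L,
      ploidy = 2L,
      mitotype = NA_character_,
      stringsAsFactors = FALSE
    ))
    list(af = af_matrix_checked(geno, provenance = "genotype_derived"),
         sheet = sheet)
  })
}
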