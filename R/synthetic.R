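#' Occupancy archetype parameters for the synthetic generator
#'
#' The generator plants four TSS-centered occupancy archetypes mirroring
#' the classes seen in neuronal H3K27me3 maps: a broad high domain spanning
#' the whole window (`broad`), a sharp Gaussian summit at the TSS
#' (`tss_strong`), a weaker summit (`tss_weak`), and unmarked background
#' (`unmarked`). A genotype effect multiplies the broad-domain amplitude by
#' `1 + delta_broad` and the summit amplitudes by `1 + delta_summit` in the
#' mutant, emulating a gain of the repressive mark over broad domains with
#' a concomitant loss at TSS summits.
#'
#' @param h_broad Plateau height of the broad class (signal units).
#' @param h_strong,h_weak Summit heights of the strong and weak TSS classes.
#' @param baseline Background signal everywhere (`b >= 0`).
#' @param sigma_strong,sigma_weak Gaussian summit widths in bp.
#' @param proportions Named class proportions summing to 1, loosely echoing
#'   observed cluster-size fractions.
#' @param delta_broad Mutant amplitude effect on the broad class (> 0).
#' @param delta_summit Mutant amplitude effect on both summit classes (< 0).
#' @return A list of class `ArchetypeParams`.
#' @export
archetype_params <- function(h_broad = 8, h_strong = 12, h_weak = 4,
                             baseline = 0.5, sigma_strong = 500,
                             sigma_weak = 500,
                             proportions = c(broad = 0.02, tss_strong = 0.10,
                                             tss_weak = 0.55,
                                             unmarked = 0.33),
                             delta_broad = 0.3, delta_summit = -0.3) {
  stopifnot(
    h_broad > baseline, h_strong > baseline, h_weak > baseline,
    h_weak < h_strong, baseline >= 0, sigma_strong > 0, sigma_weak > 0,
    abs(sum(proportions) - 1) < 1e-9,
    setequal(names(proportions),
             c("broad", "tss_strong", "tss_weak", "unmarked"))
  )
  structure(
    list(h_broad = h_broad, h_strong = h_strong, h_weak = h_weak,
         baseline = baseline, sigma_strong = sigma_strong,
         sigma_weak = sigma_weak,
         proportions = proportions[c("broad", "tss_strong", "tss_weak",
                                     "unmarked")],
         delta_broad = delta_broad, delta_summit = delta_summit),
    class = "ArchetypeParams"
  )
}

#' Simulate a refGene-style annotation
#'
#' Lays `n_genes` genes on one synthetic chromosome with alternating
#' strands. TSS positions sit on a 100-bp grid and are spaced
#' `2 * window_bp + 1200` bp apart so the occupancy windows of neighboring
#' genes never overlap.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer RNG seed (transcript lengths are drawn).
#' @param chrom Chromosome name.
#' @param chrom_length Optional chromosome length; computed from the layout
#'   when `NULL`, and an error when too short for the layout.
#' @param window_bp Half-window the layout must accommodate.
#' @return A list: `models` (gene-model data.frame, as from
#'   [select_longest_transcripts()]), `transcripts` (refGene-writable
#'   records), `chrom_length`.
#' @export
simulate_annotation <- function(n_genes, seed = 1, chrom = "chrS",
                                chrom_length = NULL, window_bp = 5000) {
  stopifnot(n_genes >= 1)
  spacing <- 2 * window_bp + 1200
  tss <- window_bp + 1000 + spacing * (seq_len(n_genes) - 1)
  tss <- 100 * ceiling(tss / 100)  # keep TSS on the 100-bp grid
  needed <- tss[n_genes] + window_bp + 1000
  if (is.null(chrom_length)) {
    chrom_length <- needed
  } else if (chrom_length < needed) {
    stop_input("simulate_annotation: chromosome too short (need >= ",
               needed, " bp)")
  }
  strand <- rep(c("+", "-"), length.out = n_genes)
  len <- with_local_seed(seed, sample(seq(2000, 8000, by = 100), n_genes,
                                      replace = TRUE))
  tx_start <- ifelse(strand == "+", tss, tss + 1 - len)
  tx_end <- ifelse(strand == "+", tss + len, tss + 1)
  gene <- sprintf("G%04d", seq_len(n_genes))
  transcripts <- data.frame(
    transcript_id = sprintf("NM_%04d", seq_len(n_genes)),
    gene_name = gene, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    stringsAsFactors = FALSE
  )
  models <- select_longest_transcripts(transcripts)
  list(models = models, transcripts = transcripts,
       chrom_length = chrom_length)
}

#' Assign archetype classes to genes
#'
#' @param models Gene-model data.frame.
#' @param params An [archetype_params()].
#' @param seed Integer RNG seed.
#' @return Ground-truth data.frame: `gene_name`, `class`.
#' @export
assign_archetypes <- function(models, params = archetype_params(),
                              seed = 1) {
  classes <- names(params$proportions)
  cls <- with_local_seed(seed, sample(classes, nrow(models), replace = TRUE,
                                      prob = params$proportions))
  data.frame(gene_name = models$gene_name, class = cls,
             stringsAsFactors = FALSE)
}

# expected scaled signal at oriented TSS offsets `off` for one class
.archetype_expectation <- function(off, class, params, genotype) {
  mut <- genotype == "Mut"
  switch(
    class,
    broad = {
      amp <- params$h_broad * (1 + if (mut) params$delta_broad else 0)
      rep(amp, length(off))
    },
    tss_strong = {
      amp <- params$h_strong * (1 + if (mut) params$delta_summit else 0)
      params$baseline + amp * exp(-off^2 / (2 * params$sigma_strong^2))
    },
    tss_weak = {
      amp <- params$h_weak * (1 + if (mut) params$delta_summit else 0)
      params$baseline + amp * exp(-off^2 / (2 * params$sigma_weak^2))
    },
    unmarked = rep(params$baseline, length(off)),
    stop_input("unknown archetype class: ", class)
  )
}

#' Simulate a genotype's coverage track
#'
#' Builds the expected signal on a 100-bp genomic grid — baseline
#' everywhere, archetype shapes across each gene's `[tss - W, tss + W)`
#' window (evaluated at bin midpoints, oriented by strand) — then draws
#' per-segment values `Poisson(expectation x depth_reads / 1e6)` so that
#' [scale_to_million()] recovers the expectation scale. `noise = "none"`
#' emits the expectation exactly (variance-zero mode).
#'
#' @param models Gene-model data.frame from [simulate_annotation()].
#' @param truth Ground truth from [assign_archetypes()] covering all genes.
#' @param params An [archetype_params()].
#' @param genotype `"WT"` or `"Mut"`.
#' @param depth_reads Declared mappable read count (depth factor
#'   `depth_reads / 1e6`).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param seed Integer RNG seed.
#' @param chrom_length Chromosome length in bp (from
#'   [simulate_annotation()]).
#' @param window_bp,bin_bp Window geometry; must match the downstream
#'   [occupancy_config()].
#' @return A list: `track` (raw, unscaled [coverage_track()]),
#'   `mappable_reads` (= `depth_reads`), `chrom_sizes` (named vector).
#' @export
simulate_track <- function(models, truth, params = archetype_params(),
                           genotype = c("WT", "Mut"), depth_reads = 5e6,
                           noise = c("poisson", "none"), seed = 1,
                           chrom_length = NULL, window_bp = 5000,
                           bin_bp = 100) {
  genotype <- match.arg(genotype)
  noise <- match.arg(noise)
  stopifnot(depth_reads > 0)
  missing <- setdiff(models$gene_name, truth$gene_name)
  if (length(missing) > 0L) {
    stop_input("simulate_track: truth lacks gene(s): ",
               paste(missing, collapse = ", "))
  }
  chrom <- unique(models$chrom)
  stopifnot(length(chrom) == 1L)
  if (is.null(chrom_length)) {
    chrom_length <- max(models$tss) + window_bp + 1000
  }
  chrom_length <- bin_bp * ceiling(chrom_length / bin_bp)
  n_seg <- chrom_length / bin_bp
  expectation <- rep(params$baseline, n_seg)
  cls <- stats::setNames(truth$class, truth$gene_name)
  nbin <- 2 * window_bp / bin_bp
  centers_plus <- seq(-window_bp + bin_bp / 2, window_bp - bin_bp / 2,
                      by = bin_bp)
  for (i in seq_len(nrow(models))) {
    tss <- models$tss[i]
    # genomic segment index range of [tss - W, tss + W)
    first <- (tss - window_bp) / bin_bp + 1
    segs <- first:(first + nbin - 1)
    ok <- segs >= 1 & segs <= n_seg
    genomic_centers <- (segs - 1) * bin_bp + bin_bp / 2
    off <- if (models$strand[i] == "+") {
      genomic_centers - tss
    } else {
      tss - genomic_centers
    }
    expectation[segs[ok]] <-
      .archetype_expectation(off[ok], cls[[models$gene_name[i]]], params,
                             genotype)
  }
  f <- depth_reads / 1e6
  values <- if (noise == "poisson") {
    with_local_seed(seed, stats::rpois(n_seg, expectation * f))
  } else {
    expectation * f
  }
  starts <- (seq_len(n_seg) - 1) * bin_bp
  keep <- values > 0
  track <- coverage_track(data.frame(
    chrom = chrom, start = starts[keep], end = starts[keep] + bin_bp,
    value = values[keep]
  ))
  list(track = track, mappable_reads = depth_reads,
       chrom_sizes = stats::setNames(chrom_length, chrom))
}

#' Simulate an unpaired WT/KO Ct table
#'
#' Reference-gene Ct is fixed at `mu_ref`; target delta-Ct is drawn
#' `Normal(mu_dct + effect * [KO], sd)`, so at `sd = 0` the KO fold is
#' exactly `2^-effect`.
#'
#' @param n_wt,n_ko Samples per arm (>= 2).
#' @param effect Planted KO shift in delta-Ct units.
#' @param sd Delta-Ct standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @param gene,reference Target and reference gene names.
#' @param mu_ref,mu_dct Reference Ct and baseline delta-Ct.
#' @return Long Ct data.frame compatible with [unpaired_expression()].
#' @export
simulate_ct <- function(n_wt, n_ko, effect = 0, sd = 0.2, seed = 1,
                        gene = "Target", reference = "Hprt",
                        mu_ref = 20, mu_dct = 2) {
  stopifnot(n_wt >= 2, n_ko >= 2, sd >= 0)
  n <- n_wt + n_ko
  arm <- rep(c("WT", "Mut"), c(n_wt, n_ko))
  dct <- with_local_seed(seed, {
    stats::rnorm(n, mean = mu_dct + effect * (arm == "Mut"), sd = sd)
  })
  sample_id <- sprintf("S%03d", seq_len(n))
  rbind(
    data.frame(sample_id = sample_id, gene = reference, ct = mu_ref,
               arm = arm, stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, gene = gene, ct = mu_ref + dct,
               arm = arm, stringsAsFactors = FALSE)
  )
}

#' Simulate a paired vehicle/drug Ct table
#'
#' Each pair's vehicle delta-Ct is drawn `Normal(mu_dct, sd_between)`; the
#' drug side adds `Normal(effect, sd)`, so at `sd = 0` every pair's fold is
#' exactly `2^-effect`.
#'
#' @param n_pairs Number of embryo pairs (>= 2).
#' @param effect Planted drug shift in delta-delta-Ct units.
#' @param sd Within-pair standard deviation (>= 0).
#' @param sd_between Between-pair delta-Ct standard deviation.
#' @param seed Integer RNG seed.
#' @param gene,reference Target and reference gene names.
#' @param mu_ref,mu_dct Reference Ct and baseline delta-Ct.
#' @return Long Ct data.frame with `pair_id`, compatible with
#'   [paired_expression()].
#' @export
simulate_ct_paired <- function(n_pairs, effect = 0, sd = 0.2,
                               sd_between = 0.5, seed = 1, gene = "Target",
                               reference = "Hprt", mu_ref = 20,
                               mu_dct = 2) {
  stopifnot(n_pairs >= 2, sd >= 0, sd_between >= 0)
  draws <- with_local_seed(seed, {
    base <- stats::rnorm(n_pairs, mu_dct, sd_between)
    shift <- stats::rnorm(n_pairs, effect, sd)
    list(v = base, d = base + shift)
  })
  pair_id <- sprintf("E%03d", seq_len(n_pairs))
  mk <- function(arm, dct) {
    rbind(
      data.frame(sample_id = paste0(pair_id, "_", arm), gene = reference,
                 ct = mu_ref, arm = arm, pair_id = pair_id,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pair_id, "_", arm), gene = gene,
                 ct = mu_ref + dct, arm = arm, pair_id = pair_id,
                 stringsAsFactors = FALSE)
    )
  }
  rbind(mk("vehicle", draws$v), mk("drug", draws$d))
}

#' Simulate a gene -> term annotation table with planted enrichment
#'
#' Generates `n_null` size-`term_size` terms drawn uniformly from the gene
#' universe, plus (when `odds > 1`) planted neuronal-style terms
#' ("synaptic ..." and a cellular-component "neuron ..." term) whose members
#' are drawn with `odds`-fold weight on `tss_strong`/`tss_weak` genes, so
#' enrichment against occupancy clusters has signal to find.
#'
#' @param truth Ground truth from [assign_archetypes()].
#' @param n_null Number of unplanted background terms.
#' @param term_size Genes per term.
#' @param odds Sampling-weight ratio for summit-class genes in planted
#'   terms; `1` disables planting (null calibration mode).
#' @param seed Integer RNG seed.
#' @return Long annotation data.frame (`gene`, `term`, `branch`).
#' @export
simulate_term_table <- function(truth, n_null = 50, term_size = 100,
                                odds = 4, seed = 1) {
  stopifnot(n_null >= 0, term_size >= 1, odds >= 1)
  genes <- truth$gene_name
  term_size <- min(term_size, length(genes))
  with_local_seed(seed, {
    out <- lapply(seq_len(n_null), function(i) {
      data.frame(gene = sample(genes, term_size),
                 term = sprintf("null process %04d", i),
                 branch = "biological_process", stringsAsFactors = FALSE)
    })
    if (odds > 1) {
      w <- ifelse(truth$class %in% c("tss_strong", "tss_weak"), odds, 1)
      planted <- list(
        c("synaptic signaling (planted)", "biological_process"),
        c("synapse organization (planted)", "biological_process"),
        c("neuron projection (planted)", "cellular_component")
      )
      out <- c(out, lapply(planted, function(p) {
        data.frame(gene = sample(genes, term_size, prob = w),
                   term = p[1L], branch = p[2L], stringsAsFactors = FALSE)
      }))
    }
    do.call(rbind, out)
  })
}

#' Simulate a complete study
#'
#' One call producing every input the pipeline consumes: annotation, ground
#' truth, WT and mutant tracks with declared read counts, a term table and
#' an unpaired Ct table. Sub-seeds are derived from `seed` so distinct
#' stages use independent streams.
#'
#' @param n_genes Number of genes.
#' @param seed Integer master seed.
#' @param params An [archetype_params()].
#' @param depth_reads Mappable reads per track.
#' @param noise Track noise mode (see [simulate_track()]).
#' @return A list: `models`, `truth`, `wt`, `mut` (each a
#'   [simulate_track()] result), `terms`, `ct`, `chrom_sizes`.
#' @export
simulate_study <- function(n_genes = 1000, seed = 1,
                           params = archetype_params(), depth_reads = 5e6,
                           noise = "poisson") {
  ann <- simulate_annotation(n_genes, seed = seed * 7 + 1)
  truth <- assign_archetypes(ann$models, params, seed = seed * 7 + 2)
  wt <- simulate_track(ann$models, truth, params, "WT", depth_reads,
                       noise, seed = seed * 7 + 3,
                       chrom_length = ann$chrom_length)
  mut <- simulate_track(ann$models, truth, params, "Mut", depth_reads,
                        noise, seed = seed * 7 + 4,
                        chrom_length = ann$chrom_length)
  terms <- simulate_term_table(truth, seed = seed * 7 + 5)
  ct <- simulate_ct(n_wt = 6, n_ko = 6, effect = 1, sd = 0.2,
                    seed = seed * 7 + 6)
  list(models = ann$models, truth = truth, wt = wt, mut = mut,
       terms = terms, ct = ct, chrom_sizes = wt$chrom_sizes)
}
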