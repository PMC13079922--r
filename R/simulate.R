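# Synthetic-data generator with planted ground truth.
#
# Generates every input the pipeline consumes: a genome with planted GGAA
# tandem runs of controlled length, two-condition peak-signal counts whose
# fold-change structure depends on repeat class (short-repeat peaks lose,
# long-repeat peaks gain signal upon STAG2 loss), replicate chromatin-loop
# calls with anchor jitter and decoys, negative-binomial expression with
# planted signature effects, and survival times whose hazard is tied to the
# signature burden.

DNA_BASES <- c("A", "C", "G", "T")

# planted per-class log2 fold-changes (condition B = STAG2-deficient vs A):
# short repeats lose EWS-FLI1 signal, long repeats gain it
default_class_effects <- function() {
  c("1x" = -1.5, "2-4x" = -0.5, "5-9x" = 0.5, ">=10x" = 1.0,
    "background" = 0)
}

truth_class <- function(unit_count) {
  ifelse(unit_count >= 10, ">=10x",
         ifelse(unit_count >= 5, "5-9x",
                ifelse(unit_count >= 2, "2-4x", "1x")))
}

#' Default synthetic study plan
#'
#' Lays out a deterministic multi-chromosome design with planted GGAA
#' repeats, genes and loop anchors arranged in non-overlapping slots:
#' 40 planted repeats per repeat class (monomeric promoter and enhancer
#' units feed the 1x signatures; multimeric units the 10x signatures, with
#' a few monomeric units at genes that are not EWS-FLI1-dependent to
#' exercise the knockdown filter), 40 background peaks, 40 background genes
#' and a STAG2 proxy gene, plus a dedicated decoy chromosome for
#' replicate-specific loop decoys.
#'
#' @param seed integer; unit counts of multimeric repeats are drawn from it.
#' @return list: `genome_spec`, `repeat_plan`, `genes`, `peak_plan`,
#'   `loop_plan`, `signature_truth`, `fli1_dependent`, `class_effects`,
#'   `seed`.
#' @export
default_study_plan <- function(seed = 1L) {
  set.seed(child_seed(seed, 101L))
  u_multi <- function(n) sample(10:15, n, replace = TRUE)
  u_24 <- function(n) sample(2:4, n, replace = TRUE)
  u_59 <- function(n) sample(5:9, n, replace = TRUE)

  slot <- function(type, width, n) {
    if (n < 1) return(NULL)
    data.frame(type = type, width = width, idx = seq_len(n))
  }
  slots <- rbind(
    slot("promP10", 10000L, 12),   # multimeric up peak in a gene promoter
    slot("promP1dep", 10000L, 12), # monomeric down peak, FLI1-dependent gene
    slot("promP1non", 10000L, 4),  # monomeric down peak, independent gene
    slot("enh10", 20000L, 12),     # multimeric up peak looped to a promoter
    slot("enh1dep", 20000L, 12),   # monomeric down peak looped, dependent
    slot("enh1non", 20000L, 4),    # monomeric down peak looped, independent
    slot("free1", 10000L, 12),     # free repeats complete the class counts
    slot("free24", 10000L, 40),
    slot("free59", 10000L, 40),
    slot("free10", 10000L, 16),
    slot("bggene", 10000L, 80),
    slot("bgpeak", 10000L, 40),
    slot("stag2", 10000L, 1))

  chrom_len <- 960000L
  chroms <- paste0("chr", 1:4)
  chrom <- character(nrow(slots)); offset <- integer(nrow(slots))
  ci <- 1L; pos <- 0L
  for (i in seq_len(nrow(slots))) {
    if (pos + slots$width[i] > chrom_len) { ci <- ci + 1L; pos <- 0L }
    chrom[i] <- chroms[ci]; offset[i] <- pos
    pos <- pos + slots$width[i]
  }
  stopifnot(ci <= length(chroms))
  slots$chrom <- chrom; slots$offset <- offset

  genome_spec <- setNames(rep(chrom_len, length(chroms)), chroms)
  genome_spec["chrD"] <- 960000L    # decoy-loop chromosome, no planted repeats

  repeats <- list(); genes <- list(); peaks <- list(); loops <- list()
  gene_of <- character(0)

  for (i in seq_len(nrow(slots))) {
    ty <- slots$type[i]; off <- slots$offset[i]; ch <- slots$chrom[i]
    k <- slots$idx[i]
    uc <- switch(ty,
                 promP10 = , enh10 = , free10 = u_multi(1),
                 promP1dep = , promP1non = , enh1dep = , enh1non = ,
                 free1 = 1L,
                 free24 = u_24(1), free59 = u_59(1), NA_integer_)
    gene_id <- switch(ty,
                      promP10 = sprintf("G10P_%02d", k),
                      promP1dep = sprintf("G1PD_%02d", k),
                      promP1non = sprintf("G1PN_%02d", k),
                      enh10 = sprintf("G10E_%02d", k),
                      enh1dep = sprintf("G1ED_%02d", k),
                      enh1non = sprintf("G1EN_%02d", k),
                      bggene = sprintf("GBG_%02d", k),
                      stag2 = "STAG2", NA_character_)
    if (ty %in% c("promP10", "promP1dep", "promP1non")) {
      tss <- off + 5000L
      rstart <- tss - 900L
      genes[[length(genes) + 1]] <- data.frame(
        gene = gene_id, chrom = ch, strand = "+", tss = tss)
      repeats[[length(repeats) + 1]] <- data.frame(
        chrom = ch, start = rstart, unit_count = uc, strand = "+")
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, center = rstart + 2L * uc, unit_count = uc,
        slot_type = ty, gene = gene_id)
    } else if (ty %in% c("enh10", "enh1dep", "enh1non")) {
      rstart <- off + 2000L
      center <- rstart + 2L * uc
      tss <- off + 12000L
      genes[[length(genes) + 1]] <- data.frame(
        gene = gene_id, chrom = ch, strand = "+", tss = tss)
      repeats[[length(repeats) + 1]] <- data.frame(
        chrom = ch, start = rstart, unit_count = uc, strand = "+")
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, center = center, unit_count = uc,
        slot_type = ty, gene = gene_id)
      loops[[length(loops) + 1]] <- data.frame(
        chrom = ch,
        a1_start = center - 1000L, a1_end = center + 1000L,
        a2_start = tss - 1750L, a2_end = tss + 250L,
        gene = gene_id, slot_type = ty)
    } else if (ty %in% c("free1", "free24", "free59", "free10")) {
      rstart <- off + 5000L
      repeats[[length(repeats) + 1]] <- data.frame(
        chrom = ch, start = rstart, unit_count = uc, strand = "+")
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, center = rstart + 2L * uc, unit_count = uc,
        slot_type = ty, gene = NA_character_)
    } else if (ty %in% c("bggene", "stag2")) {
      genes[[length(genes) + 1]] <- data.frame(
        gene = gene_id, chrom = ch, strand = "+", tss = off + 5000L)
    } else if (ty == "bgpeak") {
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, center = off + 5000L, unit_count = NA_integer_,
        slot_type = ty, gene = NA_character_)
    }
  }
  repeat_plan <- do.call(rbind, repeats)
  genes <- do.call(rbind, genes)
  peak_plan <- do.call(rbind, peaks)
  peak_plan$peak <- sprintf("peak_%03d", seq_len(nrow(peak_plan)))
  peak_plan$class <- ifelse(is.na(peak_plan$unit_count), "background",
                            truth_class(peak_plan$unit_count))
  class_effects <- default_class_effects()
  peak_plan$lfc <- unname(class_effects[peak_plan$class])
  loop_plan <- do.call(rbind, loops)
  loop_plan$peak <- peak_plan$peak[match(
    paste(loop_plan$chrom, loop_plan$a1_start + 1000L),
    paste(peak_plan$chrom, peak_plan$center))]

  pick <- function(ty) peak_plan$gene[peak_plan$slot_type == ty]
  signature_truth <- list(
    "10x_promoter" = pick("promP10"),
    "1x_promoter" = pick("promP1dep"),
    "10x_enhancer" = pick("enh10"),
    "1x_enhancer" = pick("enh1dep"),
    "prognostic_10x" = c(pick("promP10"), pick("enh10")),
    "stag2_activity_up" = c(pick("promP10"), pick("enh10")),
    "stag2_activity_down" = c(pick("promP1dep"), pick("enh1dep"), "STAG2"))
  fli1_dependent <- c(pick("promP10"), pick("enh10"),
                      pick("promP1dep"), pick("enh1dep"))

  list(genome_spec = genome_spec, repeat_plan = repeat_plan, genes = genes,
       peak_plan = peak_plan, loop_plan = loop_plan,
       signature_truth = signature_truth, fli1_dependent = fli1_dependent,
       class_effects = class_effects, seed = as.integer(seed))
}

#' Generate a genome FASTA with planted GGAA tandem runs
#'
#' Background sequence is uniform i.i.d. over A/C/G/T (no GC structure, so
#' scanner tests are unconfounded).  Planted runs are exact tandem repeats
#' of `GGAA` (`TTCC` on the minus strand).  The 50 bp flanks of every
#' planted run are regenerated until they contain no `GGAA`/`TTCC`
#' occurrence, so planted runs are maximal and recovered with their exact
#' unit counts.  Identical spec + seed gives a byte-identical file.
#'
#' @param genome_spec named integer vector: chromosome -> length (bp).
#' @param repeat_plan data.frame `chrom`, `start` (0-based), `unit_count`,
#'   `strand`; entries must fit their chromosome and be pairwise
#'   non-overlapping after unit expansion.
#' @param seed integer seed.
#' @param path output FASTA path (60-column wrap).
#' @return invisibly, a truth manifest: `genome_spec`, `planted_repeats`
#'   (with `end` column), `fasta`, `seed`.
#' @export
generate_genome <- function(genome_spec, repeat_plan, seed, path) {
  rp <- repeat_plan
  stopifnot(all(c("chrom", "start", "unit_count", "strand") %in% names(rp)))
  if (any(rp$unit_count < 1)) stopf("unit_count must be >= 1")
  rp$end <- rp$start + 4L * rp$unit_count
  unk <- setdiff(unique(rp$chrom), names(genome_spec))
  if (length(unk)) stopf("repeat plan uses unknown chromosome(s): %s",
                         paste(unk, collapse = ", "))
  if (any(rp$start < 0 | rp$end > genome_spec[rp$chrom]))
    stopf("repeat plan entry exceeds chromosome bounds")
  for (ch in unique(rp$chrom)) {
    d <- rp[rp$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) {
      ov <- which(d$start[-1] < d$end[-nrow(d)])
      if (length(ov))
        stopf("overlapping repeat plan entries on %s: [%d,%d) and [%d,%d)",
              ch, d$start[ov[1]], d$end[ov[1]],
              d$start[ov[1] + 1], d$end[ov[1] + 1])
    }
  }
  set.seed(child_seed(seed, 1L))
  con <- file(path, "wb")   # binary mode: LF endings, byte-stable
  on.exit(close(con), add = TRUE)
  for (ch in names(genome_spec)) {
    len <- genome_spec[[ch]]
    sq <- sample(DNA_BASES, len, replace = TRUE)
    d <- rp[rp$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      unit <- if (d$strand[i] == "-") c("T", "T", "C", "C")
              else c("G", "G", "A", "A")
      sq[(d$start[i] + 1L):d$end[i]] <- rep(unit, d$unit_count[i])
    }
    # scrub flanks so planted runs stay maximal and exactly recoverable
    for (i in seq_len(nrow(d))) {
      for (win in list(c(max(0L, d$start[i] - 50L), d$start[i]),
                       c(d$end[i], min(len, d$end[i] + 50L)))) {
        if (win[2] <= win[1]) next
        idx <- (win[1] + 1L):win[2]
        for (tries in 1:100) {
          w <- paste(sq[idx], collapse = "")
          if (!grepl("GGAA", w, fixed = TRUE) &&
              !grepl("TTCC", w, fixed = TRUE)) break
          sq[idx] <- sample(DNA_BASES, length(idx), replace = TRUE)
        }
      }
    }
    writeLines(c(paste0(">", ch),
                 substring(paste(sq, collapse = ""),
                           seq(1L, len, 60L),
                           pmin(seq(1L, len, 60L) + 59L, len))),
               con)
  }
  invisible(list(genome_spec = genome_spec, planted_repeats = rp,
                 fasta = path, seed = as.integer(seed)))
}

#' Generate a two-condition peak-signal experiment
#'
#' One fixed-width peak per planted repeat (centered on it) plus background
#' peaks; counts are negative binomial with a shared dispersion, means
#' respecting the planted per-class log2 fold-changes (condition B vs A)
#' and the library depths.
#'
#' @param plan study plan ([default_study_plan()]) or any list carrying
#'   `peak_plan` (`peak`, `chrom`, `center`, `class`, `lfc`).
#' @param dispersion NB dispersion (1/size); must be positive.
#' @param depth_a,depth_b library sizes (reads) of the two conditions;
#'   counts scale as depth / 16e6.
#' @param n_rep pseudo-replicates per condition.
#' @param base_mean expected normalized signal of a peak in condition A.
#' @param peak_width peak interval width (bp).
#' @param seed integer seed.
#' @return list: `peaks` (BED-style with `name`), `counts` (peaks x
#'   samples), `samples` (sample, condition, lib_size), `truth`
#'   (peak_plan with planted `lfc`).
#' @export
generate_peak_experiment <- function(plan, dispersion = 0.1,
                                     depth_a = 16e6, depth_b = 16e6,
                                     n_rep = 2L, base_mean = 500,
                                     peak_width = 400L, seed = 1L) {
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (depth_a <= 0 || depth_b <= 0) stopf("library depths must be positive")
  pp <- plan$peak_plan
  stopifnot(all(c("peak", "chrom", "center", "class", "lfc") %in% names(pp)))
  set.seed(child_seed(seed, 2L))
  half <- as.integer(peak_width / 2)
  peaks <- data.frame(chrom = pp$chrom, start = pp$center - half,
                      end = pp$center + half, name = pp$peak)
  samples <- data.frame(
    sample = c(sprintf("A_%d", seq_len(n_rep)), sprintf("B_%d", seq_len(n_rep))),
    condition = rep(c("control", "stag2_loss"), each = n_rep),
    lib_size = rep(c(depth_a, depth_b), each = n_rep))
  mu_a <- base_mean
  mu_b <- base_mean * 2^pp$lfc
  counts <- sapply(seq_len(nrow(samples)), function(j) {
    mu <- if (samples$condition[j] == "control") rep(mu_a, nrow(pp)) else mu_b
    rnbinom(nrow(pp), mu = mu * samples$lib_size[j] / 16e6,
            size = 1 / dispersion)
  })
  dimnames(counts) <- list(pp$peak, samples$sample)
  list(peaks = peaks, counts = counts, samples = samples, truth = pp)
}

#' Generate replicate loop calls with jitter, dropout and decoys
#'
#' Each replicate contains every planted loop independently dropped with
#' probability `drop_rate`, with each anchor shifted by rounded Gaussian
#' noise, plus replicate-specific decoy loops placed on a dedicated decoy
#' chromosome at interleaved lattice positions so decoys of one replicate
#' can never match the other replicate.
#'
#' @param plan study plan with `loop_plan` (`chrom`, `a1_start`, `a1_end`,
#'   `a2_start`, `a2_end`, `peak`, `gene`).
#' @param anchor_jitter_sd sd (bp) of the per-anchor jitter; must be
#'   smaller than the anchor width.
#' @param drop_rate per-replicate dropout probability.
#' @param n_decoys decoys per replicate.
#' @param decoy_chrom chromosome used for decoys.
#' @param seed integer seed.
#' @return list `rep1`, `rep2` (loop tables), `truth` (the planted
#'   loop_plan), and per-replicate logical `kept1`, `kept2`.
#' @export
generate_loops <- function(plan, anchor_jitter_sd = 100, drop_rate = 0,
                           n_decoys = 25L, decoy_chrom = "chrD", seed = 1L) {
  lp <- plan$loop_plan
  stopifnot(all(c("chrom", "a1_start", "a1_end", "a2_start", "a2_end")
                %in% names(lp)))
  aw <- min(lp$a1_end - lp$a1_start, lp$a2_end - lp$a2_start)
  if (anchor_jitter_sd >= aw)
    stopf("anchor_jitter_sd (%g) must be below the anchor width (%d)",
          anchor_jitter_sd, aw)
  stopifnot(drop_rate >= 0, drop_rate < 1)
  set.seed(child_seed(seed, 3L))
  n <- nrow(lp)
  make_rep <- function(lattice_offset) {
    keep <- runif(n) >= drop_rate
    j1 <- as.integer(round(rnorm(n, 0, anchor_jitter_sd)))
    j2 <- as.integer(round(rnorm(n, 0, anchor_jitter_sd)))
    planted <- data.frame(chrom = lp$chrom,
                          start1 = lp$a1_start + j1, end1 = lp$a1_end + j1,
                          start2 = lp$a2_start + j2, end2 = lp$a2_end + j2,
                          score = runif(n, 0.6, 1))[keep, , drop = FALSE]
    decoys <- if (n_decoys > 0) {
      s1 <- lattice_offset + (seq_len(n_decoys) - 1L) * 36000L
      data.frame(chrom = decoy_chrom,
                 start1 = s1, end1 = s1 + 2000L,
                 start2 = s1 + 8000L, end2 = s1 + 10000L,
                 score = runif(n_decoys, 0, 0.4))
    } else NULL
    list(loops = rbind(planted, decoys), kept = keep)
  }
  r1 <- make_rep(2000L)
  r2 <- make_rep(20000L)
  list(rep1 = r1$loops, rep2 = r2$loops, truth = lp,
       kept1 = r1$kept, kept2 = r2$kept)
}

#' Generate cohort expression, DE tables and survival with planted effects
#'
#' A latent per-sample STAG2-loss factor u in \[0,1\] drives planted
#' signature effects: genes of the multimeric (10x) signatures shift up by
#' `effect_log2 * u`, monomeric (1x) signature genes and the STAG2 proxy
#' gene shift down.  Survival is exponential with log-hazard
#' `hazard_beta * burden` where the burden is the standardized latent
#' factor; censoring is independent uniform calibrated to the requested
#' rate.  Differential-expression tables for the FLI1-knockdown and two
#' STAG2-knockdown model systems are produced from planted means through
#' the surrogate Welch-t test.
#'
#' @param plan study plan carrying `genes`, `signature_truth`,
#'   `fli1_dependent`.
#' @param n_samples cohort size (>= 8; quartile strata degenerate below).
#' @param nb_dispersion NB dispersion of the cohort counts.
#' @param effect_log2 planted signature log2 effect at u = 1.
#' @param hazard_beta log-hazard per unit burden.
#' @param censor_rate target fraction censored.
#' @param de_n_rep replicates per arm of the model-system contrasts.
#' @param de_effect_log2 planted log2 effect in the model-system contrasts.
#' @param base_median_months baseline median survival (months).
#' @param seed integer seed.
#' @return list: `counts`, `expression` (log2 CPM), `samples` (sample,
#'   latent, burden), `survival` (sample, time, event), `de_tables`
#'   (siFLI1_A673, shSTAG2_A673, shSTAG2_TC71), `truth`.
#' @export
generate_expression_and_survival <- function(plan, n_samples = 200L,
                                             nb_dispersion = 0.1,
                                             effect_log2 = 1.5,
                                             hazard_beta = 1,
                                             censor_rate = 0.2,
                                             de_n_rep = 6L,
                                             de_effect_log2 = 1.5,
                                             base_median_months = 36,
                                             seed = 1L) {
  if (n_samples < 8) stopf("n_samples must be >= 8 (quartile strata degenerate)")
  if (nb_dispersion <= 0) stopf("dispersion must be positive")
  st <- plan$signature_truth
  genes <- plan$genes$gene
  dir_g <- setNames(rep(0, length(genes)), genes)
  dir_g[unique(c(st$`10x_promoter`, st$`10x_enhancer`))] <- 1
  dir_g[unique(c(st$`1x_promoter`, st$`1x_enhancer`))] <- -1
  dir_g["STAG2"] <- -1

  set.seed(child_seed(seed, 4L))
  base_g <- setNames(round(stats::rlnorm(length(genes), log(300), 0.6)) + 20,
                     genes)
  u <- runif(n_samples)
  ids <- sprintf("S%03d", seq_len(n_samples))
  mu <- outer(base_g, rep(1, n_samples)) *
    2^(outer(dir_g * effect_log2, u))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   nrow = length(genes), dimnames = list(genes, ids))
  expression <- log_normalize_counts(counts)

  burden <- (u - 0.5) / sqrt(1 / 12)
  lambda0 <- log(2) / base_median_months
  t_event <- rexp(n_samples, rate = lambda0 * exp(hazard_beta * burden))
  if (censor_rate > 0) {
    # tau with P(C < T) = censor_rate at the baseline hazard
    f <- function(x) (1 - exp(-x)) / x - censor_rate
    tau <- uniroot(f, c(1e-6, 1e3))$root / lambda0
    cens <- runif(n_samples, 0, tau)
    surv <- data.frame(sample = ids, time = pmin(t_event, cens),
                       event = as.integer(t_event <= cens))
  } else {
    surv <- data.frame(sample = ids, time = t_event, event = 1L)
  }

  # model-system contrasts -> surrogate DE tables
  contrast_effect <- function(which) {
    eff <- setNames(rep(0, length(genes)), genes)
    if (which == "siFLI1") {
      eff[plan$fli1_dependent] <- -de_effect_log2
    } else {
      eff[unique(c(st$`10x_promoter`, st$`10x_enhancer`))] <- de_effect_log2
      eff[unique(c(st$`1x_promoter`, st$`1x_enhancer`))] <- -de_effect_log2
      eff["STAG2"] <- -2
    }
    eff
  }
  de_one <- function(which) {
    eff <- contrast_effect(which)
    grp <- rep(c("control", "treated"), each = de_n_rep)
    smp <- sprintf("%s_%s_%d", which, grp, c(seq_len(de_n_rep),
                                             seq_len(de_n_rep)))
    m <- outer(base_g, rep(1, 2 * de_n_rep)) *
      2^(outer(eff, as.numeric(grp == "treated")))
    cc <- matrix(rnbinom(length(m), mu = m, size = 1 / nb_dispersion),
                 nrow = length(genes), dimnames = list(genes, smp))
    # arms are generated depth-matched, so counts are already on a common
    # scale; ratio-based rescaling would be confounded by the planted DE
    # fraction
    surrogate_de(cc, setNames(grp, smp))
  }
  de_tables <- list(siFLI1_A673 = de_one("siFLI1"),
                    shSTAG2_A673 = de_one("shSTAG2_A673"),
                    shSTAG2_TC71 = de_one("shSTAG2_TC71"))

  list(counts = counts, expression = expression,
       samples = data.frame(sample = ids, latent = u, burden = burden),
       survival = surv, de_tables = de_tables,
       truth = list(direction = dir_g, effect_log2 = effect_log2,
                    hazard_beta = hazard_beta))
}

#' Simulate a complete synthetic study
#'
#' Runs all generator stages under one seed and returns every input the
#' pipeline consumes, together with the truth manifest.  When `dir` is
#' given, all artifacts are written there (FASTA, BED, TSV, bedPE-style
#' loop files, manifest JSON).
#'
#' @param seed integer master seed.
#' @param dir optional output directory.
#' @param plan study plan (defaults to [default_study_plan()] under the
#'   same seed).
#' @param peak_dispersion,peak_base_mean,n_rep peak-experiment settings.
#'   The default dispersion 0.01 keeps peak-level noise well below the
#'   signature fold-change margins so that end-to-end recovery isolates
#'   rule correctness; pass 0.1 for the noisier parameter-recovery regime.
#' @param anchor_jitter_sd,drop_rate,n_decoys loop settings.
#' @param n_samples,nb_dispersion,effect_log2,hazard_beta,censor_rate
#'   cohort settings.
#' @return list bundling all generator outputs plus `manifest`.
#' @export
simulate_study <- function(seed = 1L, dir = NULL,
                           plan = default_study_plan(seed),
                           peak_dispersion = 0.01, peak_base_mean = 500,
                           n_rep = 2L,
                           anchor_jitter_sd = 100, drop_rate = 0,
                           n_decoys = 25L,
                           n_samples = 200L, nb_dispersion = 0.1,
                           effect_log2 = 1.5, hazard_beta = 1,
                           censor_rate = 0.2) {
  fasta <- if (is.null(dir)) tempfile(fileext = ".fa")
           else file.path(dir, "genome.fa")
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gm <- generate_genome(plan$genome_spec, plan$repeat_plan, seed, fasta)
  pk <- generate_peak_experiment(plan, dispersion = peak_dispersion,
                                 base_mean = peak_base_mean,
                                 n_rep = n_rep, seed = seed)
  lo <- generate_loops(plan, anchor_jitter_sd = anchor_jitter_sd,
                       drop_rate = drop_rate, n_decoys = n_decoys,
                       seed = seed)
  ex <- generate_expression_and_survival(plan, n_samples = n_samples,
                                         nb_dispersion = nb_dispersion,
                                         effect_log2 = effect_log2,
                                         hazard_beta = hazard_beta,
                                         censor_rate = censor_rate,
                                         seed = seed)
  manifest <- list(genome_spec = as.list(plan$genome_spec),
                   planted_repeats = gm$planted_repeats,
                   planted_peaks = plan$peak_plan,
                   planted_loops = plan$loop_plan[, c("peak", "gene")],
                   signature_truth = plan$signature_truth,
                   fli1_dependent = plan$fli1_dependent,
                   class_effects = as.list(plan$class_effects),
                   hazard_beta = hazard_beta, seed = as.integer(seed))
  study <- list(fasta = fasta, plan = plan, peaks = pk$peaks,
                counts = pk$counts, samples = pk$samples,
                loops = lo, cohort = ex, manifest = manifest)
  if (!is.null(dir)) {
    write_bed(pk$peaks, file.path(dir, "peaks.bed"))
    write_tsv0(data.frame(peak = rownames(pk$counts), pk$counts,
                          check.names = FALSE),
               file.path(dir, "peak_counts.tsv"))
    write_tsv0(pk$samples, file.path(dir, "peak_samples.tsv"))
    for (r in c("rep1", "rep2")) {
      ll <- lo[[r]]
      write_tsv0(data.frame(ll$chrom, ll$start1, ll$end1,
                            ll$chrom, ll$start2, ll$end2, ll$score),
                 file.path(dir, paste0("loops_", r, ".tsv")),
                 col.names = FALSE)
    }
    write_tsv0(plan$genes, file.path(dir, "genes_tss.tsv"))
    write_tsv0(data.frame(gene = rownames(ex$counts), ex$counts,
                          check.names = FALSE),
               file.path(dir, "expression_counts.tsv"))
    write_tsv0(ex$survival, file.path(dir, "survival.tsv"))
    for (nm in names(ex$de_tables)) {
      write_tsv0(ex$de_tables[[nm]], file.path(dir, paste0("de_", nm, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  study
}

#' Jaccard index of two sets
#' @param a,b vectors treated as sets.
#' @return |a n b| / |a u b| (1 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Lattice loop plan for large-scale consensus experiments
#'
#' Builds a plan with `n_loops` planted loops laid on a regular lattice on
#' one chromosome (no genome required), for testing replicate-consensus
#' behaviour at scale.
#'
#' @param n_loops number of planted loops.
#' @param spacing lattice spacing (bp) between consecutive loops.
#' @param anchor_width,gap anchor width and gap between a loop's anchors.
#' @param chrom chromosome name.
#' @return list with `loop_plan` usable by [generate_loops()].
#' @export
loop_plan_lattice <- function(n_loops, spacing = 40000L,
                              anchor_width = 2000L, gap = 6000L,
                              chrom = "chrL") {
  s1 <- (seq_len(n_loops) - 1L) * spacing + 1000L
  lp <- data.frame(chrom = chrom,
                   a1_start = s1, a1_end = s1 + anchor_width,
                   a2_start = s1 + anchor_width + gap,
                   a2_end = s1 + 2L * anchor_width + gap,
                   gene = sprintf("G%04d", seq_len(n_loops)),
                   slot_type = "lattice",
                   peak = sprintf("peak_%04d", seq_len(n_loops)))
  list(loop_plan = lp)
}
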