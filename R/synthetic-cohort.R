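# Deterministic synthetic-cohort generator. Emulates the study design the
# analysis assumes: donors x {mock, guide treatments} x timepoints x
# technical replicates, with heterozygous/homozygous germline variants
# (binomial read sampling around VAF 0.5 / 1.0), low-VAF sequencing noise,
# optional intermediate-VAF chimerism variants, and planted on-/off-target
# edit indel spectra at stated VAFs, all over a generated reference with
# valid CDS gene models and embedded protospacer sites.

#' Cohort generator configuration
#'
#' Defaults encode the emulated study conditions: three donors, three guide
#' treatments plus mock, harvests at days 0 (mock only), 4 and 10, three
#' technical replicates, target median exon coverage 3550 with
#' negative-binomial overdispersion and a donor-specific depth factor, 120
#' germline variants per donor (two-thirds heterozygous), about one low-VAF
#' artifact variant per sample (calibrated so replicate concordance sits
#' near the panel's observed ~98%), and a planted off-target indel
#' trajectory of 21.7% (day 4) to 16.9% (day 10) total VAF alongside
#' high-efficiency on-target edits.
#'
#' @param seed Integer master seed; every derived stream is a deterministic
#'   function of it.
#' @param n_donors Number of donors.
#' @param guide_names Treatment guide names (the mock arm is always added).
#' @param timepoints_days Harvest days; day 0 produces a single mock sample
#'   per donor.
#' @param n_replicates Technical replicates per non-day-0 condition.
#' @param target_mec Target median exon coverage.
#' @param mec_dispersion Negative-binomial size parameter for per-exon mean
#'   depth (larger = less overdispersed).
#' @param donor_depth_sdlog Log-SD of the per-donor depth factor.
#' @param n_germline_per_donor Germline variants per donor.
#' @param het_fraction Fraction of germline variants that are heterozygous
#'   (true VAF 0.5; the rest are homozygous, VAF 1.0).
#' @param synonymous_fraction Fraction of germline variants engineered to be
#'   synonymous coding changes.
#' @param db_holdout_fraction Fraction of germline variants given database
#'   occurrence counts `<= 10` (so they are *not* removed by the germline
#'   filter and must be caught by mock subtraction).
#' @param noise_rate Expected artifact variants per sample (Poisson).
#' @param noise_vaf_range Uniform true-VAF range of artifact variants.
#' @param chimerism_count Intermediate-VAF donor-chimerism variants per donor
#'   (default 0; they sit in the germline database at counts > 10).
#' @param chimerism_vaf_range Uniform VAF range for chimerism variants.
#' @param planted_edits data.frame(guide, kind, match_count, vaf_d4, vaf_d10)
#'   with kind in `on_target` / `off_target`; `NULL` gives one on-target
#'   edit per guide (total VAF 0.80 / 0.75) plus one engineered off-target
#'   site (match count 20) for the last guide at the default trajectory.
#' @param indel_spectrum Named numeric vector of net indel lengths to
#'   spectrum weights (must sum to 1) applied at every planted cut site.
#' @param gene_count,cds_length,gene_gap,ref_length Reference geometry.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_donors = 3L,
                          guide_names = c("AAVS1", "HBB", "ZFPM2"),
                          timepoints_days = c(0L, 4L, 10L),
                          n_replicates = 3L,
                          target_mec = 3550,
                          mec_dispersion = 40,
                          donor_depth_sdlog = 0.1,
                          n_germline_per_donor = 120L,
                          het_fraction = 2 / 3,
                          synonymous_fraction = 0.25,
                          db_holdout_fraction = 0.05,
                          noise_rate = 1,
                          noise_vaf_range = c(5e-4, 3e-3),
                          chimerism_count = 0L,
                          chimerism_vaf_range = c(0.05, 0.35),
                          planted_edits = NULL,
                          indel_spectrum = c("-1" = 0.5, "1" = 0.25,
                                             "-2" = 0.15, "-3" = 0.10),
                          gene_count = 8L,
                          cds_length = 360L,
                          gene_gap = 600L,
                          ref_length = NULL) {
  if (is.null(planted_edits)) {
    planted_edits <- data.frame(
      guide = c(guide_names, guide_names[length(guide_names)]),
      kind = c(rep("on_target", length(guide_names)), "off_target"),
      match_count = c(rep(23L, length(guide_names)), 20L),
      vaf_d4 = c(rep(0.80, length(guide_names)), 0.217),
      vaf_d10 = c(rep(0.75, length(guide_names)), 0.169),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(n_donors >= 1L, n_replicates >= 1L, target_mec > 0,
            het_fraction >= 0, het_fraction <= 1,
            synonymous_fraction >= 0, synonymous_fraction <= 1,
            db_holdout_fraction >= 0, db_holdout_fraction <= 1,
            noise_rate >= 0, chimerism_count >= 0,
            all(planted_edits$match_count >= 0L),
            all(planted_edits$match_count <= 23L),
            all(planted_edits$vaf_d4 >= 0), all(planted_edits$vaf_d4 <= 1),
            all(planted_edits$vaf_d10 >= 0), all(planted_edits$vaf_d10 <= 1),
            abs(sum(indel_spectrum) - 1) < 1e-9,
            cds_length %% 3L == 0L)
  if (is.null(ref_length)) {
    ref_length <- gene_count * (cds_length + gene_gap) + 2L * gene_gap
  }
  structure(list(
    seed = as.integer(seed), n_donors = as.integer(n_donors),
    guide_names = guide_names, timepoints_days = as.integer(timepoints_days),
    n_replicates = as.integer(n_replicates),
    target_mec = target_mec, mec_dispersion = mec_dispersion,
    donor_depth_sdlog = donor_depth_sdlog,
    n_germline_per_donor = as.integer(n_germline_per_donor),
    het_fraction = het_fraction,
    synonymous_fraction = synonymous_fraction,
    db_holdout_fraction = db_holdout_fraction,
    noise_rate = noise_rate, noise_vaf_range = noise_vaf_range,
    chimerism_count = as.integer(chimerism_count),
    chimerism_vaf_range = chimerism_vaf_range,
    planted_edits = planted_edits,
    indel_spectrum = indel_spectrum,
    gene_count = as.integer(gene_count), cds_length = as.integer(cds_length),
    gene_gap = as.integer(gene_gap), ref_length = as.integer(ref_length)
  ), class = "cohort_config")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# 64 codons minus the three stops
non_stop_codons <- function() {
  all3 <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  setdiff(all3, STOPS)
}

#' Simulate a reference bundle
#'
#' Generates a random chromosome carrying non-overlapping CDS-only gene
#' models (valid start/stop, frame-length CDS), embeds a perfect
#' protospacer+PAM site inside a gene for each guide, and engineers one
#' partially homologous off-target site per off-target planted edit by
#' mutating `23 - match_count` positions of the guide's 23-mer (never the
#' PAM's N position). Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Seed for this stage (defaults to the config seed).
#' @return List with `reference` (`DNAStringSet`), `gene_models`, `guides`
#'   (named list of [guide_rna()]) and `sites` (data.frame of planted sites:
#'   guide, kind, gene, site_start, cut_pos, match_count).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  set.seed(seed)
  n_edit_sites <- nrow(config$planted_edits)
  if (n_edit_sites > config$gene_count) {
    stop("cannot place ", n_edit_sites, " edit sites in ",
         config$gene_count, " genes without overlap")
  }
  chrom <- "chr1"
  seq_chars <- sample(BASES, config$ref_length, replace = TRUE)

  # lay out genes on alternating strands, evenly spaced
  gene_starts <- config$gene_gap +
    (seq_len(config$gene_count) - 1L) * (config$cds_length + config$gene_gap) + 1L
  genes <- vector("list", config$gene_count)
  codons <- non_stop_codons()
  for (i in seq_len(config$gene_count)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    body <- paste(sample(codons, config$cds_length / 3L - 2L, replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", body, sample(STOPS, 1L))
    if (strand == "-") cds <- revcomp(cds)
    s <- gene_starts[i]
    seq_chars[s:(s + config$cds_length - 1L)] <- strsplit(cds, "")[[1L]]
    genes[[i]] <- gene_model(paste0("GENE", i), chrom, strand,
                             data.frame(start = s,
                                        end = s + config$cds_length - 1L))
  }

  # one protospacer per guide; sites assigned to distinct genes
  guides <- list()
  sites <- list()
  site_gene <- 0L
  for (g in config$guide_names) {
    spacer <- random_dna(20L)
    guides[[g]] <- guide_rna(g, spacer, "NGG", chrom, NA_integer_, "+")
  }
  plant_site <- function(guide, match_count, gene_idx) {
    gm <- genes[[gene_idx]]
    # 23-mer on the plus strand, placed mid-gene away from start/stop codons
    site23 <- strsplit(paste0(guides[[guide]]$spacer, "AGG"), "")[[1L]]
    if (match_count < 23L) {
      mutable <- setdiff(seq_len(23L), 21L)  # PAM N position always matches
      flip <- sample(mutable, 23L - match_count)
      for (p in flip) {
        site23[p] <- sample(setdiff(BASES, site23[p]), 1L)
      }
    }
    s <- gm$cds$start[1L] + 30L
    seq_chars[s:(s + 22L)] <<- site23
    cut <- s + 16L  # 3 bp 5' of the PAM, between protospacer pos 17 and 18
    data.frame(guide = guide, gene = gm$gene, site_start = s,
               cut_pos = cut, match_count = match_count,
               stringsAsFactors = FALSE)
  }
  pe <- config$planted_edits
  for (j in seq_len(nrow(pe))) {
    site_gene <- site_gene + 1L
    srow <- plant_site(pe$guide[j], pe$match_count[j], site_gene)
    srow$kind <- pe$kind[j]
    if (pe$kind[j] == "on_target") {
      guides[[pe$guide[j]]]$target_chrom <- chrom
      guides[[pe$guide[j]]]$cut_pos <- srow$cut_pos
    }
    sites[[j]] <- srow
  }
  sites <- do.call(rbind, sites)

  reference <- Biostrings::DNAStringSet(
    setNames(paste(seq_chars, collapse = ""), chrom))
  # embedding sites may have clobbered gene frames' start/stop; genes are
  # regenerated around sites only if broken (sites sit mid-gene, so the
  # ATG/stop anchors are untouched by construction)
  for (gm in genes) validate_gene_model(gm, reference)
  names(genes) <- vapply(genes, function(g) g$gene, character(1))
  list(reference = reference, gene_models = genes, guides = guides,
       sites = sites)
}

#' Simulate one donor's germline variants
#'
#' Draws SNVs inside CDS intervals with true VAF 0.5 (heterozygous) or 1.0
#' (homozygous); a configured fraction are synonymous substitutions by
#' construction. Every variant receives a germline-database occurrence
#' count: above 10 normally, at or below 10 for the holdout fraction.
#'
#' @param donor Donor identifier.
#' @param config A [cohort_config()].
#' @param ref_bundle Output of [simulate_reference()].
#' @param seed Stage seed.
#' @return data.frame of germline truth: chrom, pos, ref, alt, gene, effect,
#'   true_vaf, zygosity, db_count, donor.
#' @export
simulate_germline <- function(donor, config, ref_bundle, seed) {
  set.seed(seed)
  gms <- ref_bundle$gene_models
  reference <- ref_bundle$reference
  n <- config$n_germline_per_donor
  n_syn <- round(config$synonymous_fraction * n)
  edit_keep_out <- unlist(lapply(seq_len(nrow(ref_bundle$sites)), function(i) {
    seq.int(ref_bundle$sites$site_start[i] - 5L,
            ref_bundle$sites$site_start[i] + 27L)
  }))

  draw_snv <- function(want_synonymous) {
    repeat {
      gm <- gms[[sample(length(gms), 1L)]]
      pos <- sample(gm$cds$start[1L]:gm$cds$end[1L], 1L)
      if (pos %in% edit_keep_out) next
      ref <- ref_base(reference, gm$chrom, pos)
      alts <- setdiff(BASES, ref)
      effs <- vapply(alts, function(a) {
        as.character(annotate_effect(list(chrom = gm$chrom, pos = pos,
                                          ref = ref, alt = a),
                                     list(gm), reference))
      }, character(1))
      pick <- if (want_synonymous) alts[effs == "synonymous"]
              else alts[effs != "synonymous"]
      if (length(pick) == 0L) next
      alt <- sample(rep(pick, 2L), 1L)
      return(data.frame(chrom = gm$chrom, pos = pos, ref = ref, alt = alt,
                        gene = gm$gene,
                        effect = effs[match(alt, alts)],
                        stringsAsFactors = FALSE))
    }
  }
  rows <- vector("list", n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      r <- draw_snv(i <= n_syn)
      k <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
      if (!k %in% seen) { seen <- c(seen, k); rows[[i]] <- r; break }
    }
  }
  out <- do.call(rbind, rows)
  het <- runif(n) < config$het_fraction
  out$true_vaf <- ifelse(het, 0.5, 1.0)
  out$zygosity <- ifelse(het, "het", "hom")
  holdout <- runif(n) < config$db_holdout_fraction
  out$db_count <- ifelse(holdout, sample(1:10, n, replace = TRUE),
                         sample(11:5000, n, replace = TRUE))
  out$donor <- donor
  out
}

# expand planted edits into per-allele truth rows at the cut sites
expand_edit_alleles <- function(config, ref_bundle) {
  pe <- config$planted_edits
  sites <- ref_bundle$sites
  reference <- ref_bundle$reference
  spectrum <- config$indel_spectrum
  lens <- as.integer(names(spectrum))
  rows <- list()
  for (j in seq_len(nrow(pe))) {
    srow <- sites[j, ]
    for (i in seq_along(lens)) {
      net <- lens[i]
      cut <- srow$cut_pos
      chrom <- "chr1"
      if (net < 0L) {
        ref <- as.character(Biostrings::subseq(reference[[chrom]], cut,
                                               cut - net))
        alt <- substr(ref, 1L, 1L)
      } else {
        ref <- ref_base(reference, chrom, cut)
        # deterministic inserted bases: repeat the anchor's successor base
        nxt <- ref_base(reference, chrom, cut + 1L)
        alt <- paste0(ref, paste(rep(nxt, net), collapse = ""))
      }
      gm <- ref_bundle$gene_models[[srow$gene]]
      eff <- as.character(annotate_effect(list(chrom = chrom, pos = cut,
                                               ref = ref, alt = alt),
                                          list(gm), reference))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = cut, ref = ref, alt = alt,
        gene = srow$gene, effect = eff,
        guide = pe$guide[j], kind = pe$kind[j],
        match_count = pe$match_count[j],
        vaf_d4 = pe$vaf_d4[j] * spectrum[i],
        vaf_d10 = pe$vaf_d10[j] * spectrum[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # alleles at one cut site must be distinct keys
  stopifnot(!anyDuplicated(paste(out$chrom, out$pos, out$ref, out$alt,
                                 out$guide)))
  out
}

#' Simulate one sample's variant calls
#'
#' Per-exon mean depth is negative-binomial around the donor-adjusted target
#' MEC; each variant's depth is Poisson around its exon mean (floored at 1)
#' and its alt reads binomial at the true VAF. Variants drawn with zero alt
#' reads are not emitted. Noise variants (Poisson count, uniform positions,
#' uniform low VAF) are private to the sample; planted edits appear only in
#' the matching treatment arm at day > 0; mock arms carry germline, noise
#' and chimerism only.
#'
#' @param donor,treatment,timepoint,replicate Condition coordinates.
#' @param config A [cohort_config()].
#' @param truth Cohort truth bundle (see [generate_cohort()]).
#' @param seed Stage seed.
#' @return A [sample_record()].
#' @export
simulate_sample <- function(donor, treatment, timepoint, replicate, config,
                            truth, seed) {
  set.seed(seed)
  ref_bundle <- truth$ref_bundle
  gms <- ref_bundle$gene_models
  donor_factor <- truth$donor_factors[[donor]]

  exon_mean <- rnbinom(length(gms), mu = config$target_mec * donor_factor,
                       size = config$mec_dispersion) + 1
  names(exon_mean) <- names(gms)
  mec <- median(exon_mean)

  truth_rows <- truth$germline[truth$germline$donor == donor, , drop = FALSE]
  tv <- data.frame(chrom = truth_rows$chrom, pos = truth_rows$pos,
                   ref = truth_rows$ref, alt = truth_rows$alt,
                   gene = truth_rows$gene, effect = truth_rows$effect,
                   true_vaf = truth_rows$true_vaf, stringsAsFactors = FALSE)
  if (config$chimerism_count > 0L) {
    ch <- truth$chimerism[truth$chimerism$donor == donor, , drop = FALSE]
    tv <- rbind(tv, ch[, names(tv)])
  }
  if (treatment != "MOCK" && timepoint > 0L) {
    ed <- truth$edits[truth$edits$guide == treatment, , drop = FALSE]
    if (nrow(ed) > 0L) {
      vafcol <- paste0("vaf_d", timepoint)
      if (!vafcol %in% names(ed)) {
        stop("no planted VAF defined for day ", timepoint)
      }
      tv <- rbind(tv, data.frame(chrom = ed$chrom, pos = ed$pos,
                                 ref = ed$ref, alt = ed$alt, gene = ed$gene,
                                 effect = ed$effect, true_vaf = ed[[vafcol]],
                                 stringsAsFactors = FALSE))
    }
  }

  depth <- pmax(1L, rpois(nrow(tv), exon_mean[tv$gene]))
  alt_reads <- rbinom(nrow(tv), depth, tv$true_vaf)
  keep <- alt_reads > 0L
  variants <- variant_table(tv$chrom[keep], tv$pos[keep], tv$ref[keep],
                            tv$alt[keep], alt_reads[keep], depth[keep],
                            gene = tv$gene[keep], effect = tv$effect[keep])

  # sample-private low-VAF artifacts at uniform exonic positions
  n_noise <- rpois(1L, config$noise_rate)
  if (n_noise > 0L) {
    for (i in seq_len(n_noise)) {
      gm <- gms[[sample(length(gms), 1L)]]
      pos <- sample(gm$cds$start[1L]:gm$cds$end[1L], 1L)
      ref <- ref_base(ref_bundle$reference, gm$chrom, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      key <- paste(gm$chrom, pos, ref, alt, sep = ":")
      if (key %in% variant_key(variants)) next
      vaf <- runif(1L, config$noise_vaf_range[1L], config$noise_vaf_range[2L])
      d <- max(1L, rpois(1L, exon_mean[gm$gene]))
      a <- rbinom(1L, d, vaf)
      if (a == 0L) next
      eff <- as.character(annotate_effect(list(chrom = gm$chrom, pos = pos,
                                               ref = ref, alt = alt),
                                          list(gm), ref_bundle$reference))
      variants <- rbind(variants,
                        variant_table(gm$chrom, pos, ref, alt, a, d,
                                      gene = gm$gene, effect = eff))
    }
  }
  variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                             variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  sample_record(
    sample_id = sprintf("%s_%s_d%d_r%d", donor, treatment, timepoint,
                        replicate),
    donor = donor, treatment = treatment, timepoint_days = timepoint,
    replicate = replicate, variants = variants,
    median_exon_coverage = mec)
}

stage_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 97) %% 2147483646) + 1L
}

#' Generate a complete synthetic cohort
#'
#' Builds the reference bundle, per-donor germline truth, the germline
#' occurrence database, every sample of the design grid (day 0 is mock-only
#' with a single replicate; later days have every treatment at the full
#' replicate count) and the planted-variant truth table. With `out_dir` set,
#' writes the whole bundle to disk: `reference.fa`, `genes.gff3`,
#' `guides.tsv`, `germline_db.tsv`, `chip_genes.txt`, `sample_sheet.tsv`,
#' `samples/<id>.vcf`, `truth.json` and `config.yaml`. Identical config and
#' seed give byte-identical outputs.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @return List of class `synthetic_cohort`: `samples` (named list of
#'   [sample_record()]), `reference`, `gene_models`, `guides`,
#'   `germline_db`, `truth` (germline / chimerism / edits data.frames and
#'   the reference bundle), `config`.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  ref_bundle <- simulate_reference(config, seed = stage_seed(config$seed, 1L))
  donors <- paste0("D", seq_len(config$n_donors))

  set.seed(stage_seed(config$seed, 2L))
  donor_factors <- setNames(
    exp(rnorm(config$n_donors, 0, config$donor_depth_sdlog)), donors)

  germline <- do.call(rbind, lapply(seq_along(donors), function(i) {
    simulate_germline(donors[i], config, ref_bundle,
                      seed = stage_seed(config$seed, 10L + i))
  }))

  chimerism <- NULL
  if (config$chimerism_count > 0L) {
    set.seed(stage_seed(config$seed, 3L))
    chimerism <- do.call(rbind, lapply(donors, function(d) {
      rows <- lapply(seq_len(config$chimerism_count), function(i) {
        gm <- ref_bundle$gene_models[[sample(length(ref_bundle$gene_models), 1L)]]
        pos <- sample(gm$cds$start[1L]:gm$cds$end[1L], 1L)
        ref <- ref_base(ref_bundle$reference, gm$chrom, pos)
        alt <- sample(setdiff(BASES, ref), 1L)
        eff <- as.character(annotate_effect(
          list(chrom = gm$chrom, pos = pos, ref = ref, alt = alt),
          list(gm), ref_bundle$reference))
        data.frame(chrom = gm$chrom, pos = pos, ref = ref, alt = alt,
                   gene = gm$gene, effect = eff,
                   true_vaf = runif(1L, config$chimerism_vaf_range[1L],
                                    config$chimerism_vaf_range[2L]),
                   db_count = sample(11:5000, 1L), donor = d,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }

  edits <- expand_edit_alleles(config, ref_bundle)

  # germline occurrence database: union over donors (first count wins)
  db_rows <- germline[, c("chrom", "pos", "ref", "alt", "db_count")]
  if (!is.null(chimerism)) {
    db_rows <- rbind(db_rows, chimerism[, c("chrom", "pos", "ref", "alt",
                                            "db_count")])
  }
  names(db_rows)[names(db_rows) == "db_count"] <- "occurrence_count"
  db_rows <- db_rows[!duplicated(variant_key(db_rows)), , drop = FALSE]
  db_rows <- db_rows[order(db_rows$chrom, db_rows$pos, db_rows$ref,
                           db_rows$alt), , drop = FALSE]
  rownames(db_rows) <- NULL

  truth <- list(germline = germline, chimerism = chimerism, edits = edits,
                donor_factors = donor_factors, ref_bundle = ref_bundle)

  treatments <- c("MOCK", config$guide_names)
  grid <- list(); gi <- 0L
  for (d in donors) for (tp in sort(config$timepoints_days)) {
    trts <- if (tp == 0L) "MOCK" else treatments
    reps <- if (tp == 0L) 1L else config$n_replicates
    for (trt in trts) for (r in seq_len(reps)) {
      gi <- gi + 1L
      grid[[gi]] <- list(donor = d, treatment = trt, timepoint = tp,
                         replicate = r)
    }
  }
  samples <- lapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    simulate_sample(g$donor, g$treatment, g$timepoint, g$replicate, config,
                    truth, seed = stage_seed(config$seed, 100L + i))
  })
  names(samples) <- vapply(samples, function(s) s$sample_id, character(1))

  cohort <- structure(
    list(samples = samples, reference = ref_bundle$reference,
         gene_models = ref_bundle$gene_models, guides = ref_bundle$guides,
         germline_db = db_rows, truth = truth, config = config),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d donors, guides: %s\n",
              length(x$samples), x$config$n_donors,
              paste(x$config$guide_names, collapse = ", ")))
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  Biostrings::writeXStringSet(cohort$reference,
                              file.path(out_dir, "reference.fa"))
  write_gene_models(cohort$gene_models, file.path(out_dir, "genes.gff3"))
  write_guides(cohort$guides, file.path(out_dir, "guides.tsv"))
  write.table(cohort$germline_db, file.path(out_dir, "germline_db.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- do.call(rbind, lapply(cohort$samples, function(s) {
    data.frame(sample_id = s$sample_id, donor = s$donor,
               treatment = s$treatment, timepoint_days = s$timepoint_days,
               replicate = s$replicate,
               median_exon_coverage = s$median_exon_coverage,
               vcf_path = file.path("samples", paste0(s$sample_id, ".vcf")),
               stringsAsFactors = FALSE)
  }))
  write.table(sheet, file.path(out_dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c("DNMT3A", "TET2", "ASXL1", "JAK2", "TP53", "SF3B1", "SRSF2",
               "PPM1D"), file.path(out_dir, "chip_genes.txt"))
  for (s in cohort$samples) {
    write_variants(s, file.path(out_dir, "samples",
                                paste0(s$sample_id, ".vcf")), "VCF")
  }
  truth_obj <- list(germline = cohort$truth$germline,
                    chimerism = cohort$truth$chimerism,
                    edits = cohort$truth$edits,
                    donor_factors = as.list(cohort$truth$donor_factors))
  jsonlite::write_json(truth_obj, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_cohort_config(cohort$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write / read a cohort configuration as YAML
#'
#' The YAML round-trips: `read_cohort_config(write_cohort_config(cfg))`
#' reproduces every field.
#'
#' @param config A [cohort_config()].
#' @param path YAML path.
#' @return `path` invisibly (write); a `cohort_config` (read).
#' @export
write_cohort_config <- function(config, path) {
  obj <- unclass(config)
  obj$planted_edits <- lapply(seq_len(nrow(config$planted_edits)),
                              function(i) as.list(config$planted_edits[i, ]))
  obj$indel_spectrum <- as.list(config$indel_spectrum)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pe <- do.call(rbind, lapply(obj$planted_edits, as.data.frame))
  spectrum <- unlist(obj$indel_spectrum)
  do.call(cohort_config, c(
    obj[setdiff(names(obj), c("planted_edits", "indel_spectrum",
                              "ref_length"))],
    list(planted_edits = pe, indel_spectrum = spectrum,
         ref_length = obj$ref_length)))
}
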