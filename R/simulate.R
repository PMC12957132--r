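#' Default recurrent-mutation frequency spectrum
#'
#' A variant-level carrier-probability spectrum emulating a colorectal
#' tumor cohort: a few high-frequency drivers (KRAS G12D 6%, BRAF V600E
#' 5.2%, KRAS G13D 3.9%, KRAS G12V 3.5%, hotspot TP53/PIK3CA/APC variants)
#' followed by a long tail down to recurrence-level frequencies (~0.7%,
#' i.e. 2 patients of 308). Includes frameshift truncation groups
#' (RNF43 G659X, ARID1A G1848X) and nonsense variants so every consequence
#' class is exercised.
#'
#' @param n_tail Number of additional low-frequency tail mutations
#'   (default 16).
#' @return Data frame: `mutation_id`, `gene`, `protein_change`,
#'   `consequence`, `carrier_prob`.
#' @export
default_mutation_spectrum <- function(n_tail = 16L) {
  head <- data.frame(
    gene = c("KRAS", "BRAF", "KRAS", "KRAS", "TP53", "PIK3CA", "TP53",
             "APC", "PIK3CA", "RNF43", "SMAD4", "FBXW7", "TP53", "NRAS",
             "ARID1A", "TCF7L2", "ERG", "AKAP9", "APC", "KRAS"),
    protein_change = c("G12D", "V600E", "G13D", "G12V", "R175H", "E545K",
                       "R273H", "R1450*", "H1047R", "G659X", "R361H",
                       "R465C", "R282W", "Q61K", "G1848X", "L200X",
                       "A454X", "K39X", "R876*", "A146T"),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "missense", "missense", "nonsense",
                    "missense", "frameshift", "missense", "missense",
                    "missense", "missense", "frameshift", "frameshift",
                    "frameshift", "frameshift", "nonsense", "missense"),
    carrier_prob = c(0.060, 0.052, 0.039, 0.035, 0.030, 0.028, 0.025,
                     0.022, 0.020, 0.019, 0.018, 0.016, 0.015, 0.014,
                     0.013, 0.012, 0.012, 0.011, 0.011, 0.010),
    stringsAsFactors = FALSE
  )
  if (n_tail > 0) {
    tail_genes <- paste0("TGENE", seq_len(n_tail))
    tail <- data.frame(
      gene = tail_genes,
      protein_change = sprintf("A%dV", 40 + seq_len(n_tail)),
      consequence = "missense",
      carrier_prob = round(seq(0.010, 0.007, length.out = n_tail), 4),
      stringsAsFactors = FALSE
    )
    head <- rbind(head, tail)
  }
  head$mutation_id <- paste0(head$gene, "_", head$protein_change)
  head[, c("mutation_id", "gene", "protein_change", "consequence",
           "carrier_prob")]
}

#' Gene annotations matching [default_mutation_spectrum()]
#'
#' Cancer-gene roles and hallmark flags for the simulated genes; tail genes
#' are hallmark-annotated so they survive the catalog's gene filter.
#'
#' @param spectrum A mutation spectrum data frame.
#' @return Data frame `gene`, `role`, `hallmark`.
#' @export
default_gene_annotations <- function(spectrum = default_mutation_spectrum()) {
  roles <- c(KRAS = "oncogene", BRAF = "oncogene", NRAS = "oncogene",
             PIK3CA = "oncogene", ERG = "oncogene",
             TP53 = "TSG", APC = "TSG", RNF43 = "TSG", SMAD4 = "TSG",
             FBXW7 = "TSG", ARID1A = "TSG",
             TCF7L2 = "dual", AKAP9 = "dual")
  genes <- unique(spectrum$gene)
  role <- unname(roles[genes])
  role[is.na(role)] <- "TSG"
  data.frame(gene = genes, role = role, hallmark = TRUE,
             stringsAsFactors = FALSE)
}

#' Build a simulation specification
#'
#' Defaults describe the emulated study: a discovery cohort of 308 tumors
#' with the [default_mutation_spectrum()], one planted co-occurring pair
#' (BRAF V600E with the RNF43 G659X truncation group, odds ratio 18.7,
#' echoing the co-mutation structure of hypermutated colorectal tumors),
#' MSI-H prevalence 15%, and diploid HLA genotypes drawn from a population
#' allele-frequency table under Hardy-Weinberg proportions with independent
#' loci.
#'
#' @param n_patients Cohort size (default 308).
#' @param spectrum Mutation spectrum data frame (see
#'   [default_mutation_spectrum()]).
#' @param comut_pairs Data frame `mut1`, `mut2`, `odds_ratio` of planted
#'   co-mutation pairs (default one pair, OR 18.7); `NULL` for none.
#' @param msi_prevalence Probability of MSI-H status (default 0.15).
#' @param genotype_table An `allele_freq_table` (single population) used to
#'   draw genotypes; `NULL` disables genotype simulation.
#' @param vaf_range VAF range for simulated variants (default
#'   `c(0.05, 0.6)`).
#' @param seed Mandatory integer seed.
#' @return List of class `sim_spec`.
#' @export
simulation_spec <- function(n_patients = 308L,
                            spectrum = default_mutation_spectrum(),
                            comut_pairs = data.frame(
                              mut1 = "BRAF_V600E", mut2 = "RNF43_G659X",
                              odds_ratio = 18.7, stringsAsFactors = FALSE),
                            msi_prevalence = 0.15,
                            genotype_table = NULL,
                            vaf_range = c(0.05, 0.6),
                            seed) {
  if (missing(seed)) stop_arg("seed is mandatory")
  if (any(spectrum$carrier_prob < 0 | spectrum$carrier_prob > 1)) {
    stop_arg("carrier probabilities must lie in [0,1]")
  }
  if (msi_prevalence < 0 || msi_prevalence > 1) {
    stop_arg("msi_prevalence must lie in [0,1]")
  }
  structure(list(
    n_patients = as.integer(n_patients), spectrum = spectrum,
    comut_pairs = comut_pairs, msi_prevalence = msi_prevalence,
    genotype_table = genotype_table, vaf_range = vaf_range,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

# joint carriage probabilities for two Bernoulli margins at a target odds
# ratio (Plackett construction)
.joint_p11 <- function(pA, pB, or) {
  if (or == 1) return(pA * pB)
  s <- 1 + (pA + pB) * (or - 1)
  p11 <- (s - sqrt(s^2 - 4 * or * (or - 1) * pA * pB)) / (2 * (or - 1))
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  if (is.nan(p11) || p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop_arg("infeasible odds-ratio construction for margins %.3f/%.3f", pA, pB)
  }
  min(max(p11, lo), hi)
}

#' Simulate a tumor cohort with planted ground truth
#'
#' Each patient's mutations are drawn independently from the spectrum's
#' carrier probabilities, except planted co-mutation pairs, which are drawn
#' jointly from the 2x2 distribution with the requested odds ratio. VAFs
#' are uniform on `vaf_range`; MSI-H status is assigned by prevalence and
#' expanded into five consistent marker calls; two alleles per locus are
#' drawn i.i.d. from the genotype table (Hardy-Weinberg, independent loci),
#' with residual per-locus frequency mass assigned to an `XX*99:99`
#' placeholder allele. The whole draw is a pure function of the spec's
#' seed.
#'
#' @param spec A `sim_spec`.
#' @return List with `patients` (list of `neo_patient`), `variants` (data
#'   frame in the simple dialect of [read_maf()]), and `truth` (carriage
#'   matrix, genotypes, MSI status and the spec itself).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    sp <- spec$spectrum
    m <- nrow(sp)
    carry <- matrix(FALSE, n, m, dimnames = list(NULL, sp$mutation_id))
    for (j in seq_len(m)) carry[, j] <- stats::runif(n) < sp$carrier_prob[j]
    if (!is.null(spec$comut_pairs) && nrow(spec$comut_pairs)) {
      for (r in seq_len(nrow(spec$comut_pairs))) {
        m1 <- spec$comut_pairs$mut1[r]; m2 <- spec$comut_pairs$mut2[r]
        if (!all(c(m1, m2) %in% sp$mutation_id)) {
          stop_arg("planted pair names unknown mutation(s): %s/%s", m1, m2)
        }
        pA <- sp$carrier_prob[sp$mutation_id == m1]
        pB <- sp$carrier_prob[sp$mutation_id == m2]
        p11 <- .joint_p11(pA, pB, spec$comut_pairs$odds_ratio[r])
        u <- stats::runif(n)
        both <- u < p11
        aonly <- u >= p11 & u < p11 + (pA - p11)
        bonly <- u >= p11 + (pA - p11) & u < p11 + (pA - p11) + (pB - p11)
        carry[, m1] <- both | aonly
        carry[, m2] <- both | bonly
      }
    }
    patient_ids <- sprintf("P%03d", seq_len(n))
    # variant rows with VAFs
    rows <- which(carry, arr.ind = TRUE)
    variants <- data.frame(
      sample_id = patient_ids[rows[, 1]],
      gene = sp$gene[rows[, 2]],
      protein_change = sp$protein_change[rows[, 2]],
      consequence = sp$consequence[rows[, 2]],
      vaf = round(stats::runif(nrow(rows), spec$vaf_range[1],
                               spec$vaf_range[2]), 4),
      stringsAsFactors = FALSE
    )
    variants$mutation_id <- paste0(variants$gene, "_",
                                   variants$protein_change)
    variants <- variants[order(variants$sample_id, variants$mutation_id), ,
                         drop = FALSE]
    rownames(variants) <- NULL
    # genotypes
    genotypes <- rep(list(character()), n)
    if (!is.null(spec$genotype_table)) {
      tab <- spec$genotype_table
      cols <- list()
      for (loc in c("A", "B", "C")) {
        ls <- tab[tab$locus == loc, , drop = FALSE]
        if (!nrow(ls)) next
        resid <- max(0, 1 - sum(ls$frequency))
        pool <- c(ls$allele, paste0(loc, "*99:99"))
        pr <- c(ls$frequency, resid)
        cols[[loc]] <- matrix(sample(pool, 2 * n, replace = TRUE,
                                     prob = pr), ncol = 2)
      }
      if (length(cols)) {
        gm <- do.call(cbind, cols)
        genotypes <- lapply(seq_len(n), function(i) gm[i, ])
      }
    }
    # MSI status and consistent markers
    msi_h <- stats::runif(n) < spec$msi_prevalence
    markers <- lapply(seq_len(n), function(i) {
      k <- if (msi_h[i]) 2L + stats::rbinom(1, 3, 0.5)
           else stats::rbinom(1, 1, 0.3)
      sample(c(rep(TRUE, k), rep(FALSE, 5 - k)))
    })
    patients <- lapply(seq_len(n), function(i) {
      make_patient(patient_ids[i],
                   mutations = sp$mutation_id[carry[i, ]],
                   hla_genotype = genotypes[[i]] %||% character(),
                   msi_markers = markers[[i]])
    })
    list(patients = patients, variants = variants,
         truth = list(spec = spec, carriage = carry,
                      msi_h = msi_h, patient_ids = patient_ids))
  })
}

#' Write a simulated variant table in the TCGA MAF column dialect
#'
#' @param variants Simulated variant data frame from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  back <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
            frameshift = "Frame_Shift_Del", other = "Silent")
  df <- data.frame(
    Hugo_Symbol = variants$gene,
    Tumor_Sample_Barcode = variants$sample_id,
    HGVSp_Short = paste0("p.", variants$protein_change),
    Variant_Classification = unname(back[variants$consequence]),
    VAF = variants$vaf,
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Simulate wild-type proteins consistent with a mutation spectrum
#'
#' Random proteins over the 20-letter alphabet, long enough to hold every
#' mutation position plus flanking sequence for 25-mer windows, with the
#' reference residue at each mutation position forced to match the
#' mutation's reference letter. Frameshift mutations receive random novel
#' tails of 10-30 residues.
#'
#' @param spectrum Mutation spectrum data frame.
#' @param seed Integer seed.
#' @param flank Residues appended beyond the furthest mutation position
#'   (default 40).
#' @return List with `proteins` (named character, per gene) and `tails`
#'   (named character, per frameshift mutation id).
#' @export
simulate_proteins <- function(spectrum, seed, flank = 40L) {
  pc <- parse_protein_change(spectrum$protein_change)
  if (any(!pc$parsed)) stop_arg("spectrum has unparseable protein changes")
  with_seed(seed, {
    proteins <- character()
    for (g in unique(spectrum$gene)) {
      idx <- which(spectrum$gene == g)
      L <- max(pc$pos[idx]) + flank
      chars <- sample(.AA, L, replace = TRUE)
      for (i in idx) chars[pc$pos[i]] <- pc$ref[i]
      # conflicting reference letters at a shared position are a spec error
      for (p in unique(pc$pos[idx])) {
        refs <- unique(pc$ref[idx][pc$pos[idx] == p])
        if (length(refs) > 1) {
          stop_arg("gene %s has conflicting reference residues at position %d",
                   g, p)
        }
      }
      proteins[g] <- paste(chars, collapse = "")
    }
    tails <- character()
    fs <- which(pc$alt == "X")
    for (i in fs) {
      tails[spectrum$mutation_id[i]] <-
        paste(sample(.AA, sample(10:30, 1), replace = TRUE), collapse = "")
    }
    list(proteins = proteins, tails = tails)
  })
}

#' Simulate a random per-country allele-frequency table
#'
#' Used for property tests of the coverage models: per locus, allele
#' frequencies are a normalized random simplex scaled to a total mass
#' below 1.
#'
#' @param seed Integer seed.
#' @param n_alleles Named integer vector of alleles per locus.
#' @param total_mass Per-locus frequency mass (default drawn in
#'   \[0.8, 0.98\]).
#' @param population Population label.
#' @return An `allele_freq_table`-shaped data frame.
#' @export
simulate_allele_table <- function(seed, n_alleles = c(A = 8, B = 10, C = 6),
                                  total_mass = NULL, population = "Sim") {
  with_seed(seed, {
    rows <- list()
    for (loc in names(n_alleles)) {
      k <- n_alleles[[loc]]
      w <- stats::rexp(k)
      mass <- total_mass %||% stats::runif(1, 0.8, 0.98)
      f <- w / sum(w) * mass
      rows[[loc]] <- data.frame(
        population = population, locus = loc,
        allele = sprintf("%s*%02d:01", loc, seq_len(k)),
        frequency = f, n_eff = 1000, stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    class(tab) <- c("allele_freq_table", class(tab))
    tab
  })
}

#' Simulate diploid genotypes from an allele-frequency table
#'
#' Two alleles per locus drawn i.i.d. (Hardy-Weinberg), loci independent;
#' residual frequency mass goes to a `XX*99:99` placeholder.
#'
#' @param n Number of individuals.
#' @param table Allele-frequency table (single population).
#' @param seed Integer seed.
#' @return List of character vectors (up to 6 alleles each).
#' @export
simulate_genotypes <- function(n, table, seed) {
  with_seed(seed, {
    cols <- list()
    for (loc in unique(table$locus)) {
      ls <- table[table$locus == loc, , drop = FALSE]
      resid <- max(0, 1 - sum(ls$frequency))
      pool <- c(ls$allele, paste0(loc, "*99:99"))
      pr <- c(ls$frequency, resid)
      cols[[loc]] <- matrix(sample(pool, 2 * n, replace = TRUE, prob = pr),
                            ncol = 2)
    }
    m <- do.call(cbind, cols)
    lapply(seq_len(n), function(i) m[i, ])
  })
}

#' Simulate an ELISpot mutant / wild-type well pair
#'
#' Counts come from a negative-binomial model (overdispersed Poisson
#' mixture): the wild-type well has mean `baseline`, the mutant well mean
#' `baseline * effect` when the pair is truly reactive and `baseline`
#' otherwise. The default dispersion (`size = 100`) corresponds to mild
#' overdispersion as seen in spot counts pooled over replicate wells; it is
#' calibrated so a 3-fold true effect at a baseline of 20 spots is called
#' reactive in over 90% of draws while non-reactive pairs are called in
#' under 10%.
#'
#' @param reactive Logical ground truth.
#' @param baseline Mean wild-type spot count (> 0, default 20).
#' @param effect True mutant/wild-type fold effect (default 3).
#' @param dispersion Negative-binomial size parameter (default 10).
#' @param seed Integer seed.
#' @return List with `mut_spots`, `wt_spots`.
#' @export
simulate_elispot <- function(reactive, baseline = 20, effect = 3,
                             dispersion = 100, seed) {
  if (baseline <= 0) stop_arg("baseline must be > 0")
  with_seed(seed, {
    wt <- stats::rnbinom(1, mu = baseline, size = dispersion)
    mu_mut <- baseline * if (reactive) effect else 1
    mut <- stats::rnbinom(1, mu = mu_mut, size = dispersion)
    list(mut_spots = mut, wt_spots = wt)
  })
}

#' Deterministic binding landscape with planted separation
#'
#' Generates best-rank binding calls for every (mutation, allele)
#' combination via [synthetic_predict()] on the mutation's peptides.
#' Planted pairs receive strong-binder ranks; when `separate = TRUE`
#' (default) unplanted pairs whose hashed rank falls below `binder_rank`
#' are re-hashed with an incremented salt until they land at or above it,
#' so the planted set is exactly the set of binders — the ground-truth
#' closure used by the recovery tests.
#'
#' @param peptides Data frame of peptide pairs (from
#'   [mutation_peptides()]), with `mutation_id` and `mut_peptide`.
#' @param alleles Character vector of alleles to score against.
#' @param planted Data frame `mutation_id`, `allele` of planted binders
#'   (may be `NULL`).
#' @param seed Integer seed.
#' @param binder_rank,strong_rank Thresholds (2 and 0.5).
#' @param separate Enforce planted/unplanted separation (default TRUE).
#' @return Data frame `mutation_id`, `allele`, `rank` (best rank per pair).
#' @export
simulate_binding <- function(peptides, alleles, planted = NULL, seed,
                             binder_rank = 2, strong_rank = 0.5,
                             separate = TRUE) {
  alleles <- normalize_allele(alleles)
  muts <- unique(peptides$mutation_id)
  grid <- expand.grid(mutation_id = muts, allele = alleles,
                      stringsAsFactors = FALSE)
  pkey <- if (is.null(planted)) character() else
    paste(planted$mutation_id, normalize_allele(planted$allele), sep = "|")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    mid <- grid$mutation_id[i]; al <- grid$allele[i]
    peps <- peptides$mut_peptide[peptides$mutation_id == mid]
    is_planted <- paste(mid, al, sep = "|") %in% pkey
    ranks <- synthetic_predict(peps, al, seed = seed,
                               mutation_id = rep(mid, length(peps)),
                               planted = if (is_planted) planted else NULL,
                               strong_rank = strong_rank)
    best <- min(ranks)
    if (!is_planted && separate) {
      salt <- 0L
      while (best < binder_rank && salt < 1000L) {
        salt <- salt + 1L
        ranks <- synthetic_predict(peps, al, seed = seed, salt = salt)
        best <- min(ranks)
      }
    }
    data.frame(mutation_id = mid, allele = al, rank = best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
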