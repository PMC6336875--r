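## Synthetic-data generator: reference gene, ground-truth site classes,
## insertion library, sorted-pool counts, junction reads, protein-property
## tables and flow-cytometry events — every input the pipeline consumes,
## with known parameters so downstream stages can be tested without the
## deposited sequencing data.

#' Generate a random reference coding sequence
#'
#' Builds a stand-in CDS for the profiled channel: starts with ATG, contains
#' no in-frame stop codon except the final one, and has `n_residues` codons
#' in total. With `n_residues = 437` the library positions used by
#' [simulate_library()] yield 435 scoreable internal sites, mirroring the
#' 435 candidate positions of Kir2.1.
#'
#' @param n_residues number of codons (including initiator and terminal stop);
#'   must be at least 10
#' @param seed integer seed; output is deterministic given the seed
#' @return a `dip_reference`: list with `cds` (character) and `n_residues`
#' @export
make_reference <- function(n_residues, seed = 1) {
  if (!is.numeric(n_residues) || n_residues < 10) {
    stop_invalid("n_residues must be >= 10")
  }
  n_residues <- as.integer(n_residues)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  codons <- with_seed(seed, {
    out <- character(n_residues)
    out[1] <- "ATG"
    out[n_residues] <- "TAA"
    for (i in seq(2, n_residues - 1)) {
      repeat {
        cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
        if (!cd %in% stops) break
      }
      out[i] <- cd
    }
    out
  })
  structure(list(cds = paste(codons, collapse = ""), n_residues = n_residues),
            class = "dip_reference")
}

.ref_cds <- function(reference) {
  if (inherits(reference, "dip_reference")) reference$cds
  else as.character(reference)
}

#' Define an insertion cassette (domain plus flanking linkers)
#'
#' The inserted payload is `linker_n + domain + linker_c`; the default
#' linkers are Ala-Ser on the N side and Gly-Ser-Ala on the C side. Exactly
#' one of `insert_aa` / `insert_nt` may be given the other is derived
#' (nucleotide from a fixed codon table, or amino acid by translation); if
#' both are given they must agree.
#'
#' @param name cassette identifier (e.g. `"PDZ"`)
#' @param insert_aa amino-acid sequence of the domain
#' @param insert_nt nucleotide sequence of the domain
#' @param linker_n,linker_c linker amino acids (lengths 2 and 3)
#' @return a `dip_cassette` with `full_nt`, the complete inserted sequence
#' @export
dip_cassette <- function(name, insert_aa = NULL, insert_nt = NULL,
                         linker_n = "AS", linker_c = "GSA") {
  if (is.null(insert_aa) && is.null(insert_nt)) {
    stop_invalid("one of insert_aa / insert_nt is required")
  }
  if (is.null(insert_nt)) insert_nt <- reverse_translate(insert_aa)
  if (is.null(insert_aa)) insert_aa <- translate_nt(insert_nt)
  if (translate_nt(insert_nt) != insert_aa) {
    stop_invalid("insert_nt does not translate to insert_aa")
  }
  if (nchar(linker_n) != 2 || nchar(linker_c) != 3) {
    stop_invalid("linkers must be 2 (N-side) and 3 (C-side) amino acids")
  }
  full_nt <- paste0(reverse_translate(linker_n), insert_nt,
                    reverse_translate(linker_c))
  structure(list(name = name, insert_aa = insert_aa, insert_nt = insert_nt,
                 linker_n = linker_n, linker_c = linker_c, full_nt = full_nt),
            class = "dip_cassette")
}

.cassette_nt <- function(cassette) {
  if (inherits(cassette, "dip_cassette")) cassette$full_nt
  else as.character(cassette)
}

#' Example domain cassettes
#'
#' Two synthetic cassettes with random (stop-free) 60-residue domains,
#' labelled after the PDZ and Cib81 domains the profiling compares. The
#' sequences are random stand-ins, not the real domains.
#'
#' @param names cassette names
#' @param seed integer seed
#' @param n_aa domain length in residues
#' @return named list of `dip_cassette`
#' @export
example_cassettes <- function(names = c("PDZ", "Cib81"), seed = 101,
                              n_aa = 60) {
  aas <- names(.codon_table)
  out <- lapply(seq_along(names), function(i) {
    aa <- with_seed(derive_seed(seed, i),
                    paste(sample(aas, n_aa, replace = TRUE), collapse = ""))
    dip_cassette(names[i], insert_aa = aa)
  })
  stats::setNames(out, names)
}

#' Simulation configuration
#'
#' @param seed integer master seed
#' @param n_variants library complexity (cells/variants drawn per library)
#' @param depth_per_pool sequencing reads per sorted pool
#' @param n_replicates replicate count (the study design is triplicate)
#' @param bias_amplitude `b` of the 5'-depressed positional weight
#'   `w(p) = 1 - b * exp(-p / lambda)`, in `[0, 1)`
#' @param bias_length_scale `lambda` of the positional weight, in nt
#' @param read_length simulated read length, nt
#' @param error_rate per-base substitution probability
#' @param min_anchor minimum exact anchor length used by the junction caller
#' @return a `dip_config` list
#' @export
sim_config <- function(seed = 1, n_variants = 1e5, depth_per_pool = 2e5,
                       n_replicates = 3, bias_amplitude = 0.8,
                       bias_length_scale = 150, read_length = 50,
                       error_rate = 0, min_anchor = 15) {
  if (depth_per_pool < 1) stop_invalid("depth_per_pool must be >= 1")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (bias_amplitude < 0 || bias_amplitude >= 1) {
    stop_invalid("bias_amplitude must be in [0, 1)")
  }
  if (error_rate < 0 || error_rate > 1) stop_invalid("error_rate in [0, 1]")
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 depth_per_pool = as.integer(depth_per_pool),
                 n_replicates = as.integer(n_replicates),
                 bias_amplitude = bias_amplitude,
                 bias_length_scale = bias_length_scale,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 min_anchor = as.integer(min_anchor)),
            class = "dip_config")
}

#' Default ground-truth class fractions
#'
#' Permissive 0.40, scaffold (structurally intolerant) 0.35, differential
#' `n_differential / n_sites`, intermediate (partial trafficking) the
#' remainder. With 435 sites and the default 40 differential sites the
#' largest-remainder allocation in [simulate_truth()] produces exactly 40
#' differential sites. The composition is chosen so that (i) the
#' surface-expression probabilities span several well-separated levels —a
#' rank spectrum a rank-based recovery analysis can resolve— and (ii) no
#' class sits near the enrichment zero-crossing (the library-mean p_se,
#' ~0.41 under these defaults), where binarization is unstable by
#' construction.
#'
#' @param n_sites number of scoreable sites
#' @param n_differential differential sites wanted
#' @return named fractions summing to 1
#' @export
default_class_fractions <- function(n_sites = 435, n_differential = 40) {
  f_diff <- n_differential / n_sites
  c(permissive = 0.40, scaffold = 0.35, differential = f_diff,
    intermediate = 1 - 0.40 - 0.35 - f_diff)
}

#' Assign ground-truth site classes and surface-expression probabilities
#'
#' Every scoreable site (residues `1 .. n_residues - 2`) is assigned one of
#' four classes encoding the three permissibility categories plus an
#' intermediate band: `permissive` (p_se 0.8 for every domain), `scaffold`
#' (0.05), `intermediate` (0.25), and `differential` (p_se gap between
#' domains: one randomly chosen domain at `p_se_high`, the others at
#' `p_se_low`). Class counts follow a largest-remainder allocation of
#' `class_fractions`, then classes are shuffled over positions.
#'
#' @param reference a `dip_reference`
#' @param class_fractions named fractions over the four classes, summing to 1
#' @param p_se_table optional named list `class -> probability` overriding the
#'   defaults for the non-differential classes
#' @param domains character vector of domain names
#' @param p_se_high,p_se_low differential-site probabilities (default gap 0.6)
#' @param seed integer seed
#' @return a `dip_truth` data frame: `aa_pos`, `site_class`, one
#'   `p_se_<domain>` column per domain
#' @export
simulate_truth <- function(reference,
                           class_fractions = default_class_fractions(
                             reference$n_residues - 2),
                           p_se_table = NULL,
                           domains = c("PDZ", "Cib81"),
                           p_se_high = 0.7, p_se_low = 0.1,
                           seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop_invalid("class_fractions must sum to 1")
  }
  classes <- c("permissive", "scaffold", "differential", "intermediate")
  frac <- stats::setNames(rep(0, 4), classes)
  frac[names(class_fractions)] <- class_fractions
  defaults <- list(permissive = 0.8, scaffold = 0.05, intermediate = 0.25)
  if (!is.null(p_se_table)) defaults[names(p_se_table)] <- p_se_table

  n_sites <- reference$n_residues - 2L
  # largest-remainder allocation so counts are exact for exact fractions
  raw <- frac * n_sites
  cnt <- floor(raw)
  rem <- n_sites - sum(cnt)
  if (rem > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[idx] <- cnt[idx] + 1
  }
  with_seed(seed, {
    site_class <- sample(rep(classes, times = cnt))
    p_se <- matrix(NA_real_, nrow = n_sites, ncol = length(domains),
                   dimnames = list(NULL, domains))
    for (cl in c("permissive", "scaffold", "intermediate")) {
      p_se[site_class == cl, ] <- defaults[[cl]]
    }
    d_idx <- which(site_class == "differential")
    for (i in d_idx) {
      hi <- sample(seq_along(domains), 1)
      p_se[i, ] <- p_se_low
      p_se[i, hi] <- p_se_high
    }
    out <- data.frame(aa_pos = seq_len(n_sites), site_class = site_class,
                      stringsAsFactors = FALSE)
    for (d in domains) out[[paste0("p_se_", d)]] <- p_se[, d]
    structure(out, domains = domains, class = c("dip_truth", "data.frame"))
  })
}

#' Extract the site-by-domain surface-expression probability matrix
#'
#' @param truth a `dip_truth`
#' @return matrix sites x domains, rownames = `aa_pos`
#' @export
p_se_matrix <- function(truth) {
  domains <- attr(truth, "domains")
  m <- as.matrix(truth[, paste0("p_se_", domains), drop = FALSE])
  dimnames(m) <- list(truth$aa_pos, domains)
  m
}

#' Simulate a transposon insertion library
#'
#' Insertion nucleotide positions span `3 .. length(cds) - 6` (all three
#' frames, both orientations; insertions before the initiator codon and into
#' the final codons are excluded) and are drawn with the 5'-depressed MuA
#' weight `w(p) = 1 - b * exp(-p / lambda)`. Orientation is uniform; counts
#' are multinomial with `n_variants` trials.
#'
#' @param reference a `dip_reference`
#' @param config a `dip_config`
#' @param seed integer seed (defaults to the config seed)
#' @return data frame `nt_pos` (0-based), `orientation`
#'   (`"forward"`/`"reverse"`), `count` (> 0 rows only)
#' @export
simulate_library <- function(reference, config, seed = config$seed) {
  cds_len <- nchar(.ref_cds(reference))
  pos <- seq(3L, cds_len - 6L)
  w <- 1 - config$bias_amplitude * exp(-pos / config$bias_length_scale)
  cells <- data.frame(
    nt_pos = rep(pos, 2L),
    orientation = rep(c("forward", "reverse"), each = length(pos)),
    stringsAsFactors = FALSE)
  prob <- rep(w, 2L)
  prob <- prob / sum(prob)
  if (config$n_variants == 0) {
    return(cells[integer(0), c("nt_pos", "orientation")] |>
             transform(count = integer(0)))
  }
  cnt <- with_seed(seed, as.integer(rmultinom(1, config$n_variants, prob)))
  cells$count <- cnt
  out <- cells[cells$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample productive read counts
#'
#' Container for the per-residue productive read counts `r_i` of one sorted
#' pool and the pool total `t` (the Eq.-level `r` and `t`).
#'
#' @param aa_pos integer residue indices (1-based; 0 = before residue 1)
#' @param count non-negative integer read counts aligned with `aa_pos`
#' @param pool pool label (`"SE"`, `"NSE"`, `"control"`)
#' @param replicate replicate id
#' @param domain domain name
#' @return a `dip_counts` list with `t = sum(count)`
#' @export
dip_counts <- function(aa_pos, count, pool = NA_character_,
                       replicate = NA_integer_, domain = NA_character_) {
  if (length(aa_pos) != length(count)) stop_invalid("length mismatch")
  if (any(count < 0)) stop_invalid("negative counts")
  structure(list(aa_pos = as.integer(aa_pos), count = as.integer(count),
                 t = sum(as.numeric(count)), pool = pool,
                 replicate = replicate, domain = domain),
            class = "dip_counts")
}

#' Simulate FACS sorting and pool sequencing for one replicate
#'
#' Productive library variants (forward orientation, frame 0) are split into
#' surface-expressed (SE) and not-surface-expressed (NSE) cells binomially
#' with the site's ground-truth `p_se` for the given domain; each pool is
#' then sequenced to `depth_per_pool` reads multinomially over its cell
#' counts.
#'
#' @param library output of [simulate_library()]
#' @param truth a `dip_truth`
#' @param domain domain name (must be present in `truth`)
#' @param config a `dip_config`
#' @param replicate_seed integer seed for this replicate
#' @param replicate replicate id stored in the outputs
#' @return list with `dip_counts` elements `se` and `nse` on the full site
#'   grid of `truth`
#' @export
simulate_sort_counts <- function(library, truth, domain, config,
                                 replicate_seed, replicate = NA_integer_) {
  domains <- attr(truth, "domains")
  if (!domain %in% domains) {
    stop_invalid("domain '", domain, "' not present in truth")
  }
  prod <- library[library$orientation == "forward" &
                    library$nt_pos %% 3 == 0, , drop = FALSE]
  prod$aa_pos <- prod$nt_pos %/% 3
  prod <- prod[prod$aa_pos %in% truth$aa_pos, , drop = FALSE]
  p <- truth[[paste0("p_se_", domain)]][match(prod$aa_pos, truth$aa_pos)]
  with_seed(replicate_seed, {
    se_cells <- rbinom(nrow(prod), prod$count, p)
    nse_cells <- prod$count - se_cells
    draw <- function(cells) {
      if (sum(cells) == 0) return(integer(length(cells)))
      as.integer(rmultinom(1, config$depth_per_pool, cells))
    }
    se_reads <- draw(se_cells)
    nse_reads <- draw(nse_cells)
    grid <- function(reads, pool) {
      cnt <- integer(nrow(truth))
      cnt[match(prod$aa_pos, truth$aa_pos)] <- reads
      dip_counts(truth$aa_pos, cnt, pool = pool, replicate = replicate,
                 domain = domain)
    }
    list(se = grid(se_reads, "SE"), nse = grid(nse_reads, "NSE"))
  })
}

.mutate_read <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < error_rate)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulate junction read pairs for a library
#'
#' Each library variant occurrence yields one read pair spanning its two
#' insertion junctions. The insertion allele is
#' `cds[1..p+5] + insert + cds[p+1..]` (0-based `p`; the 5-bp target-site
#' duplication `cds[p+1..p+5]` flanks the insert on both sides). Read 1
#' covers the upstream junction (reference flank ending at `p+5`, then the
#' cassette 5' end); read 2 covers the downstream junction and is emitted
#' reverse-complemented, as the bottom-strand mate. Reverse-orientation
#' variants insert the reverse complement of the cassette. Read ids encode
#' the ground truth (`v<k>:nt<p>:<F|R>`) for test oracles.
#'
#' @param library output of [simulate_library()]
#' @param reference a `dip_reference`
#' @param cassette a `dip_cassette` (its `full_nt` is inserted)
#' @param config a `dip_config` (`read_length`, `error_rate`, `min_anchor`)
#' @param seed integer seed (substitution errors only)
#' @return list of character vectors `id`, `r1`, `r2`
#' @export
simulate_reads <- function(library, reference, cassette, config,
                           seed = config$seed) {
  cds <- .ref_cds(reference)
  L <- config$read_length
  if (L < 2 * config$min_anchor) {
    stop_invalid("read_length must be >= 2 * min_anchor")
  }
  ins_f <- .cassette_nt(cassette)
  if (nchar(ins_f) < L) stop_invalid("cassette shorter than read_length")
  ins_r <- revcomp(ins_f)
  flank <- L %/% 2
  n_pairs <- sum(library$count)
  id <- character(n_pairs); r1 <- character(n_pairs); r2 <- character(n_pairs)
  k <- 0L
  with_seed(seed, {
    for (row in seq_len(nrow(library))) {
      p <- library$nt_pos[row]
      orient <- library$orientation[row]
      ins <- if (orient == "forward") ins_f else ins_r
      nI <- nchar(ins)
      up_flank <- substr(cds, max(1L, p + 5L - flank + 1L), p + 5L)
      read1 <- paste0(up_flank, substr(ins, 1L, L - nchar(up_flank)))
      down_flank <- substr(cds, p + 1L, min(nchar(cds), p + flank))
      ins_tail <- substr(ins, nI - (L - nchar(down_flank)) + 1L, nI)
      read2 <- revcomp(paste0(ins_tail, down_flank))
      for (j in seq_len(library$count[row])) {
        k <- k + 1L
        id[k] <- sprintf("v%06d:nt%d:%s", k, p,
                         if (orient == "forward") "F" else "R")
        r1[k] <- .mutate_read(read1, config$error_rate)
        r2[k] <- .mutate_read(read2, config$error_rate)
      }
    }
  })
  list(id = id, r1 = r1, r2 = r2)
}

#' Write / read FASTQ (plain 4-line records, Phred+33)
#'
#' Error-free bases are written with quality "I" (Q40).
#'
#' @param ids,seqs record ids and sequences
#' @param path file path
#' @return `write_fastq` the path, invisibly; `read_fastq` a list of
#'   `id` and `seq`
#' @export
write_fastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(id = names(x), seq = unname(as.character(x)))
}

#' Parse ground truth from simulated read ids
#'
#' @param ids read ids produced by [simulate_reads()]
#' @return data frame `nt_pos`, `orientation`
#' @export
truth_from_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  data.frame(
    nt_pos = as.integer(sub("^nt", "", vapply(parts, `[`, "", 2L))),
    orientation = ifelse(vapply(parts, `[`, "", 3L) == "F",
                         "forward", "reverse"),
    stringsAsFactors = FALSE)
}

#' Simulate a protein-property feature table
#'
#' Features come in the three categories of the property analysis: static
#' (default 5: crystallographic/packing-type descriptors), conservation
#' (default 21: a conservation score plus predicted mutation effects), and
#' dynamic (default 20, mimicking the first 20 normal modes). Only dynamic
#' features carry signal, emulating mobility-like properties that are
#' depressed at rigid scaffold sites and elevated at flexible permissive
#' sites relative to the protein average: each site gets a class-dependent
#' level — the site's mean surface-expression propensity rescaled to
#' `[-1, 1]` (scaffold -1, permissive +1, partial classes in between) — and
#' dynamic feature k is `sign_k * effect_size * level + N(0, 1)` with signs
#' alternating across modes. Static and conservation features are pure unit
#' Gaussian noise, independent of class.
#'
#' @param truth a `dip_truth`
#' @param effect_size shift magnitude in SD units
#' @param n_static,n_conservation,n_dynamic feature counts per category
#' @param seed integer seed
#' @return a `dip_features` data frame (rows = sites, rownames = `aa_pos`)
#'   with attribute `categories` (named character vector feature -> category)
#' @export
simulate_features <- function(truth, effect_size = 1.0, n_static = 5,
                              n_conservation = 21, n_dynamic = 20, seed = 1) {
  if (min(n_static, n_conservation, n_dynamic) < 1) {
    stop_invalid("feature counts must be >= 1")
  }
  n <- nrow(truth)
  propensity <- rowMeans(p_se_matrix(truth))
  rng <- range(propensity)
  shift <- if (diff(rng) > 0) {
    2 * (propensity - rng[1]) / diff(rng) - 1
  } else {
    rep(0, n)
  }
  static_names <- if (n_static == 5) {
    c("b_factor", "packing_10A", "packing_4.5A_intra", "packing_4.5A_inter",
      "surface_exposure")
  } else sprintf("static_%d", seq_len(n_static))
  cons_names <- sprintf("conservation_%d", seq_len(n_conservation))
  dyn_names <- sprintf("mode_%d", seq_len(n_dynamic))
  with_seed(seed, {
    m_static <- matrix(rnorm(n * n_static), n)
    m_cons <- matrix(rnorm(n * n_conservation), n)
    sgn <- rep(c(1, -1), length.out = n_dynamic)
    m_dyn <- vapply(seq_len(n_dynamic),
                    function(k) sgn[k] * effect_size * shift + rnorm(n),
                    numeric(n))
    out <- data.frame(m_static, m_cons, m_dyn)
    names(out) <- c(static_names, cons_names, dyn_names)
    rownames(out) <- truth$aa_pos
    structure(out,
              categories = stats::setNames(
                rep(c("static", "conservation", "dynamic"),
                    c(n_static, n_conservation, n_dynamic)),
                names(out)),
              class = c("dip_features", "data.frame"))
  })
}

#' Simulate a flow-cytometry event set
#'
#' Voltage-dye (DiBAC-like) intensities are a two-component log-normal
#' mixture: a hyperpolarized (low-dye) component with meanlog `log(150)` and
#' a depolarized component with meanlog `log(1500)`, both sdlog 0.4. The
#' hyperpolarized weight is `activity * (1 + light_shift) * g(k_ext)` with
#' `g(k) = 1 / (1 + (k / 25)^2)` decreasing in external K+ (mM): raising K+
#' depolarizes the population. Fluorescence channels (dye, marker) decay
#' multiplicatively with acquisition index as `exp(-bleach_rate * t_acq)`
#' (photobleaching); scatter channels are fixed log-normals.
#'
#' @param activity channel activity in `[0, 1]` (fraction of maximal
#'   hyperpolarizing function)
#' @param k_ext external K+ concentration, mM
#' @param light_shift multiplicative change of activity under illumination
#' @param bleach_rate photobleaching rate per event index
#' @param n_events number of events
#' @param seed integer seed
#' @return a `dip_flow` data frame with columns `fsc_a`, `fsc_h`, `fsc_w`,
#'   `ssc_a`, `marker`, `dye`, `t_acq`
#' @export
simulate_flow <- function(activity, k_ext = 2, light_shift = 0,
                          bleach_rate = 0, n_events = 10000, seed = 1) {
  if (activity < 0 || activity > 1) stop_invalid("activity must be in [0, 1]")
  if (n_events < 1) stop_invalid("n_events must be >= 1")
  g <- 1 / (1 + (k_ext / 25)^2)
  w_hyper <- min(1, activity * (1 + light_shift)) * g
  with_seed(seed, {
    comp <- rbinom(n_events, 1, w_hyper)
    dye0 <- rlnorm(n_events, meanlog = ifelse(comp == 1, log(150), log(1500)),
                   sdlog = 0.4)
    t_acq <- seq_len(n_events) - 1L
    decay <- exp(-bleach_rate * t_acq)
    fsc_a <- rlnorm(n_events, log(5e4), 0.25)
    out <- data.frame(
      fsc_a = fsc_a,
      fsc_h = fsc_a * rlnorm(n_events, 0, 0.05),
      fsc_w = rlnorm(n_events, log(80), 0.1),
      ssc_a = rlnorm(n_events, log(3e4), 0.3),
      marker = rlnorm(n_events, log(2e3), 0.5) * decay,
      dye = dye0 * decay,
      t_acq = t_acq)
    structure(out, class = c("dip_flow", "data.frame"))
  })
}
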