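# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate an age-structured beta cohort
#'
#' Generates synthetic (beta, age) cohorts matching the clock's statistical
#' assumptions, for parameter-recovery work and demos. Two generative modes:
#'
#' * `"uniform"` (default): betas i.i.d. uniform on \[0,1\] per CpG, then
#'   `age = clock(beta) + N(0, noise_sd^2)`. This makes the clock formula the
#'   true regression function, so OLS refitting should recover its
#'   coefficients.
#' * `"age_driven"`: chronological age drawn uniform over `age_range`, betas
#'   generated as clipped linear functions of age with slopes sign-matched to
#'   the clock weights (two sites rising, one falling with age) plus Gaussian
#'   beta noise. A more lifelike marginal structure for demonstrations; no
#'   claim of matching real cohort distributions.
#'
#' Ages are clipped to `>= 0` and clipped samples flagged; the truth table
#' records pre-clip ages.
#'
#' @param model An [epiage_clock()] acting as the generative formula.
#' @param n Number of samples.
#' @param noise_sd SD of the Gaussian age noise, years (uniform mode) /
#'   of the beta noise (age_driven mode uses 0.03 beta units).
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @param mode `"uniform"` or `"age_driven"`.
#' @param age_range Age span for `"age_driven"` mode, years.
#' @return List with `beta` (n x CpG matrix), `samples` (data frame
#'   `sample_id`, `age`), and `truth` (data frame with `age_pre_clip`,
#'   `clipped`).
#' @export
simulate_cohort <- function(model, n, noise_sd = 5, seed,
                            mode = c("uniform", "age_driven"),
                            age_range = c(0, 103)) {
  stopifnot(inherits(model, "epiage_clock"))
  mode <- match.arg(mode)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  k <- length(model$cpg_ids)
  ids <- sprintf("sim_%05d", seq_len(n))
  .with_seed(seed, {
    if (mode == "uniform") {
      beta <- matrix(stats::runif(n * k), nrow = n,
                     dimnames = list(ids, model$cpg_ids))
      age_true <- predict_age(model, beta) +
        stats::rnorm(n, 0, noise_sd)
    } else {
      age <- stats::runif(n, age_range[1], age_range[2])
      base <- ifelse(model$weights > 0, 0.05, 0.85)
      slope <- ifelse(model$weights > 0, 0.0085, -0.0075)
      beta <- sapply(seq_len(k), function(j)
        pmin(1, pmax(0, base[j] + slope[j] * age + stats::rnorm(n, 0, 0.03))))
      dimnames(beta) <- list(ids, model$cpg_ids)
      age_true <- age
    }
    clipped <- age_true < 0
    list(beta = beta,
         samples = data.frame(sample_id = ids, age = pmax(0, age_true),
                              stringsAsFactors = FALSE),
         truth = data.frame(sample_id = ids, age_pre_clip = age_true,
                            clipped = clipped, stringsAsFactors = FALSE))
  })
}

#' Simulate technical replicate beta sets
#'
#' Emulates repeated NGS runs of the same samples: per replicate, betas are
#' the truth betas plus Gaussian noise, clipped to \[0,1\].
#'
#' @param beta Truth betas: named vector (one sample) or samples x CpG
#'   matrix with row names as sample ids.
#' @param n_replicates Replicates per sample (>= 2).
#' @param beta_noise_sd SD of the per-replicate beta noise.
#' @param seed Integer seed.
#' @return A list of `replicate_set` objects, one per sample, each with
#'   `sample_id` and `betas` (replicates x CpG matrix).
#' @export
simulate_replicates <- function(beta, n_replicates = 4L, beta_noise_sd = 0.01,
                                seed) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  if (is.null(dim(beta)))
    beta <- matrix(beta, nrow = 1L,
                   dimnames = list("sample_1", names(beta)))
  if (any(beta < 0 | beta > 1))
    stop("truth betas must be in [0,1]", call. = FALSE)
  .with_seed(seed, {
    lapply(seq_len(nrow(beta)), function(i) {
      reps <- matrix(rep(beta[i, ], each = n_replicates) +
                       stats::rnorm(n_replicates * ncol(beta), 0, beta_noise_sd),
                     nrow = n_replicates,
                     dimnames = list(NULL, colnames(beta)))
      reps[] <- pmin(1, pmax(0, reps))   # [] keeps the matrix shape
      structure(list(sample_id = rownames(beta)[i], betas = reps),
                class = "replicate_set")
    })
  })
}

#' Simulate UMI-tagged bisulfite amplicon read pairs
#'
#' Generates paired reads from an amplicon under a simple directional-library
#' model. Per molecule: each annotated CpG is methylated with its given
#' probability; bisulfite conversion turns every unmethylated cytosine
#' (CpG or not — the non-CpG background is fully unmethylated) into `T` with
#' probability `conversion_efficiency`, while methylated CpG cytosines stay
#' `C`. Each molecule gets a UMI (distinct across molecules by construction)
#' and a geometric number of PCR copies with mean `duplication_rate`, all
#' sharing the UMI. Read 1 is the UMI followed by the first `read_length`
#' bases of the converted top strand; read 2 is the reverse complement of its
#' last `read_length` bases. Per-base substitution errors are applied to the
#' genomic bases of each copy independently (not to the UMI — UMI error
#' correction is out of scope, so the truth table stays exact). Base
#' qualities are constant Q37.
#'
#' @param reference An [amplicon_reference()].
#' @param n_molecules Number of original molecules.
#' @param meth_probs Per-CpG methylation probabilities in \[0,1\] (recycled
#'   to the number of annotated CpGs).
#' @param duplication_rate Mean PCR copies per molecule (>= 1).
#' @param conversion_efficiency Bisulfite conversion probability in \[0,1\].
#' @param error_rate Per-base substitution error probability in \[0,1).
#' @param read_length Genomic bases per read (<= amplicon length).
#' @param seed Integer seed (mandatory).
#' @return List with `pairs` (a [read_pairs()] table) and `truth` (list:
#'   `molecules` data frame with `molecule_id`, `umi`, `n_copies`; `states`
#'   molecules x CpG logical methylation matrix; `params`).
#' @export
simulate_reads <- function(reference, n_molecules, meth_probs,
                           duplication_rate = 1, conversion_efficiency = 1,
                           error_rate = 0, read_length = 250L, seed) {
  stopifnot(inherits(reference, "amplicon_reference"))
  if (missing(seed)) stop("seed is required for reproducibility", call. = FALSE)
  L <- nchar(reference$sequence)
  if (read_length > L)
    stop("read_length longer than amplicon (", L, " bp)", call. = FALSE)
  n_cpg <- length(reference$cpg_offsets)
  meth_probs <- rep_len(as.numeric(meth_probs), n_cpg)
  if (any(meth_probs < 0 | meth_probs > 1))
    stop("meth_probs must be in [0,1]", call. = FALSE)
  if (duplication_rate < 1)
    stop("duplication_rate must be >= 1", call. = FALSE)
  if (conversion_efficiency < 0 || conversion_efficiency > 1)
    stop("conversion_efficiency must be in [0,1]", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0,1)", call. = FALSE)

  ref_chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  c_pos <- which(ref_chars == "C")                 # 1-based
  cpg_pos <- reference$cpg_offsets + 1L
  bases <- c("A", "C", "G", "T")

  .with_seed(seed, {
    # distinct UMIs by construction: resample collisions
    draw_umis <- function(n, k) {
      if (k == 0L) return(rep("", n))
      u <- replicate(n, paste(sample(bases, k, replace = TRUE), collapse = ""))
      while (anyDuplicated(u)) {
        dup <- which(duplicated(u))
        u[dup] <- replicate(length(dup),
                            paste(sample(bases, k, replace = TRUE),
                                  collapse = ""))
      }
      u
    }
    umis <- draw_umis(n_molecules, reference$umi_length)
    states <- matrix(stats::runif(n_molecules * n_cpg) <
                       rep(meth_probs, each = n_molecules),
                     nrow = n_molecules,
                     dimnames = list(NULL, reference$cpg_ids))
    n_copies <- 1L + stats::rgeom(n_molecules, prob = 1 / duplication_rate)

    add_errors <- function(chars) {
      hit <- which(stats::runif(length(chars)) < error_rate)
      if (length(hit))
        chars[hit] <- vapply(chars[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      chars
    }

    ids <- seqs1 <- quals1 <- seqs2 <- quals2 <- vector("list", n_molecules)
    q37 <- strrep(rawToChar(as.raw(33L + 37L)), read_length)
    for (m in seq_len(n_molecules)) {
      conv <- ref_chars
      unmeth_c <- setdiff(c_pos, cpg_pos[states[m, ]])
      converted <- unmeth_c[stats::runif(length(unmeth_c)) <
                              conversion_efficiency]
      conv[converted] <- "T"
      fwd <- conv[seq_len(read_length)]
      rev_src <- conv[(L - read_length + 1L):L]
      kc <- n_copies[m]
      s1 <- s2 <- character(kc)
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      for (cpy in seq_len(kc)) {
        f <- if (error_rate > 0) add_errors(fwd) else fwd
        r <- if (error_rate > 0) add_errors(rev_src) else rev_src
        s1[cpy] <- paste0(umis[m], paste(f, collapse = ""))
        s2[cpy] <- paste(rev(unname(comp[r])), collapse = "")
      }
      ids[[m]] <- sprintf("mol%05d:copy%d", m, seq_len(kc))
      seqs1[[m]] <- s1
      seqs2[[m]] <- s2
      quals1[[m]] <- rep(strrep(rawToChar(as.raw(33L + 37L)),
                                reference$umi_length + read_length), kc)
      quals2[[m]] <- rep(q37, kc)
    }
    pairs <- read_pairs(unlist(ids), unlist(seqs1), unlist(quals1),
                        unlist(seqs2), unlist(quals2))
    list(pairs = pairs,
         truth = list(
           molecules = data.frame(molecule_id = sprintf("mol%05d",
                                                        seq_len(n_molecules)),
                                  umi = umis, n_copies = n_copies,
                                  stringsAsFactors = FALSE),
           states = states,
           params = list(n_molecules = n_molecules, meth_probs = meth_probs,
                         duplication_rate = duplication_rate,
                         conversion_efficiency = conversion_efficiency,
                         error_rate = error_rate, read_length = read_length,
                         seed = seed)))
  })
}
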