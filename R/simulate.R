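BASES <- c("A", "C", "G", "T")

#' Simulation specification for synthetic amplicon reads
#'
#' Describes a mixture of mutant haplotypes sequenced to ultra-deep coverage
#' on a single amplicon, with an error model mimicking the two library
#' regimes: \code{"native"} cfDNA and \code{"wga2"} (whole-genome-amplified),
#' the latter carrying a roughly tenfold higher substitution background.
#'
#' Two error sources are injected after each read's haplotype is assigned:
#' \itemize{
#'   \item a per-position, per-alternate-base background rate drawn once per
#'     dataset from a Gamma distribution (\code{background$mean} in fraction
#'     units, \code{background$shape}), modelling locus-specific amplification
#'     noise;
#'   \item a uniform per-base sequencing error rate \code{base_error_rate}.
#' }
#' Haplotype bases receive \code{quality$true_q}; injected error bases receive
#' \code{quality$error_q} except for a fraction \code{quality$error_hi_frac}
#' of "high-quality errors" at \code{quality$error_hi_q}, so that downstream
#' quality filtering is non-trivially exercised.
#'
#' @param reference nucleotide string (A/C/G/T, length 100-2000).
#' @param haplotypes list of haplotypes, each \code{list(subs = , freq = )}
#'   where \code{subs} is a named character vector mapping 1-based positions
#'   to alternate bases (1-2 substitutions typical) and \code{freq} a fraction
#'   in [0, 1]. Frequencies must sum to at most 1; the remainder is wild type.
#' @param n_reads number of reads to simulate.
#' @param read_length \code{NULL} for full-length reads, a single integer for
#'   fixed-length reads with random start offsets, or \code{c(min, max)} for
#'   uniform lengths.
#' @param base_error_rate per-base sequencing substitution probability.
#' @param regime \code{"native"} or \code{"wga2"}; selects the default
#'   background profile.
#' @param background \code{list(mean = , shape = )} overriding the regime
#'   default (fraction units; defaults: native 3e-4, wga2 3e-3, shape 2).
#' @param quality \code{list(true_q, error_q, error_hi_q, error_hi_frac)};
#'   default Phred 35 / 15 / 30 / 0.10.
#' @param mapq \code{list(values = , probs = )} mapping-quality distribution;
#'   default 95\% at 60 with small mass at 18 and 10 (excluded by the default
#'   mapping filter).
#' @param seed integer seed; fully determines the dataset.
#' @return an object of class \code{"sim_spec"}.
#' @seealso [simulate_amplicon()]
#' @export
sim_spec <- function(reference,
                     haplotypes = list(),
                     n_reads = 10000L,
                     read_length = NULL,
                     base_error_rate = 1e-3,
                     regime = c("native", "wga2"),
                     background = NULL,
                     quality = NULL,
                     mapq = NULL,
                     seed = 1L) {
  regime <- match.arg(regime)
  reference <- toupper(reference)
  if (!grepl("^[ACGT]+$", reference))
    stop("reference must contain only A/C/G/T")
  L <- nchar(reference)
  if (L < 100L || L > 2000L)
    stop("reference length must be in [100, 2000]")
  if (is.null(background))
    background <- list(mean = if (regime == "wga2") 3e-3 else 3e-4, shape = 2)
  if (is.null(quality))
    quality <- list(true_q = 35L, error_q = 15L, error_hi_q = 30L,
                    error_hi_frac = 0.10)
  if (is.null(mapq))
    mapq <- list(values = c(60L, 18L, 10L), probs = c(0.95, 0.03, 0.02))
  freqs <- vapply(haplotypes, function(h) as.numeric(h$freq), numeric(1))
  if (length(freqs) && any(freqs < 0))
    stop("haplotype frequencies must be non-negative")
  if (sum(freqs) > 1 + 1e-12)
    stop("haplotype frequencies sum to more than 1")
  ref_chars <- strsplit(reference, "")[[1]]
  for (h in haplotypes) {
    pos <- as.integer(names(h$subs))
    if (anyNA(pos) || any(pos < 1L) || any(pos > L))
      stop("substitution position outside the reference")
    if (anyDuplicated(pos))
      stop("overlapping substitutions at the same position within one haplotype")
    alt <- toupper(as.character(h$subs))
    if (!all(alt %in% BASES))
      stop("alternate alleles must be A/C/G/T")
    if (any(alt == ref_chars[pos]))
      stop("alternate allele equals the reference base")
  }
  if (!is.null(read_length)) {
    read_length <- as.integer(read_length)
    if (!length(read_length) %in% 1:2 || any(read_length < 1L) ||
        max(read_length) > L)
      stop("read_length must be one or two integers within the reference length")
    if (length(read_length) == 2L && read_length[1] > read_length[2])
      stop("read_length range must be increasing")
  }
  stopifnot(n_reads >= 1, base_error_rate >= 0, base_error_rate < 1,
            background$mean >= 0, background$shape > 0,
            abs(sum(mapq$probs) - 1) < 1e-8)
  structure(list(reference = reference, haplotypes = haplotypes,
                 n_reads = as.integer(n_reads), read_length = read_length,
                 base_error_rate = base_error_rate, regime = regime,
                 background = background, quality = quality, mapq = mapq,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Random amplicon reference sequence
#'
#' @param length sequence length.
#' @param seed integer seed.
#' @param gc target GC fraction.
#' @return a nucleotide string.
#' @export
random_reference <- function(length = 300L, seed = 1L, gc = 0.5) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Simulate an aligned ultra-deep amplicon read set
#'
#' Draws each read from the haplotype mixture, injects regime-dependent
#' background substitutions and sequencing errors after haplotype assignment,
#' assigns per-base Phred qualities and per-read mapping qualities, and
#' records per-read mismatch counts against the reference (the SAM NM value).
#' Reads are emitted pre-aligned and gapless with known 1-based start
#' coordinates. Identical spec (including seed) yields an identical dataset.
#'
#' @param spec a [sim_spec()].
#' @return a list of class \code{"amplicon_sim"} with elements
#'   \describe{
#'     \item{reads}{data.frame: \code{id}, \code{start}, \code{end},
#'       \code{seq}, \code{qual} (Phred+33), \code{mapq}, \code{nm}.}
#'     \item{truth}{list: specified haplotype frequencies, realized
#'       per-haplotype read counts (wild type included), the realized
#'       per-position background error-rate matrix, and the seed.}
#'     \item{reference}{the reference string.}
#'   }
#' @examples
#' ref <- random_reference(150, seed = 7)
#' spec <- sim_spec(ref, list(list(subs = c("50" = alt_base(ref, 50)),
#'                                 freq = 0.1)),
#'                  n_reads = 500, seed = 7)
#' sim <- simulate_amplicon(spec)
#' sim$truth$realized_counts
#' @export
simulate_amplicon <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ref_chars <- strsplit(spec$reference, "")[[1]]
  ref_code <- match(ref_chars, BASES)
  L <- length(ref_code)
  n <- spec$n_reads
  H <- length(spec$haplotypes)
  freqs <- vapply(spec$haplotypes, function(h) h$freq, numeric(1))

  # haplotype assignment (0 = wild type)
  hap <- if (H) {
    sample.int(H + 1L, n, replace = TRUE, prob = c(1 - sum(freqs), freqs)) - 1L
  } else rep(0L, n)
  realized <- tabulate(hap + 1L, nbins = H + 1L)

  # read coordinates
  if (is.null(spec$read_length)) {
    len <- rep(L, n); start <- rep(1L, n)
  } else {
    len <- if (length(spec$read_length) == 1L) {
      rep(spec$read_length, n)
    } else {
      lens <- seq(spec$read_length[1], spec$read_length[2])
      lens[sample.int(length(lens), n, replace = TRUE)]
    }
    start <- 1L + floor(stats::runif(n) * (L - len + 1L))
  }

  # per-dataset background rates: positions x 3 alternate bases
  bg <- spec$background
  rate <- matrix(if (bg$mean > 0)
                   stats::rgamma(3L * L, shape = bg$shape,
                                 scale = bg$mean / bg$shape)
                 else 0,
                 nrow = L, ncol = 3L)
  alt_code <- t(vapply(ref_code, function(r) setdiff(1:4, r), integer(3)))

  # flatten all read bases
  B <- sum(len)
  ridx <- rep.int(seq_len(n), len)
  pos <- unlist(lapply(seq_len(n), function(i) seq.int(start[i],
                                                       length.out = len[i])),
                use.names = FALSE)
  base <- ref_code[pos]
  for (h in seq_len(H)) {
    subs <- spec$haplotypes[[h]]$subs
    sel <- hap[ridx] == h
    for (j in seq_along(subs)) {
      p <- as.integer(names(subs)[j])
      base[sel & pos == p] <- match(toupper(subs[[j]]), BASES)
    }
  }
  true_base <- base

  # background substitutions (toward reference-alternate bases)
  tot_rate <- rate[, 1] + rate[, 2] + rate[, 3]
  if (any(tot_rate > 0)) {
    flip <- stats::runif(B) < tot_rate[pos]
    if (any(flip)) {
      fp <- pos[flip]
      u <- stats::runif(sum(flip)) * tot_rate[fp]
      which_alt <- 1L + (u > rate[fp, 1]) + (u > rate[fp, 1] + rate[fp, 2])
      base[flip] <- alt_code[cbind(fp, which_alt)]
    }
  }
  # uniform sequencing errors (away from the current base)
  if (spec$base_error_rate > 0) {
    err <- stats::runif(B) < spec$base_error_rate
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      base[err] <- ((base[err] - 1L + shift) %% 4L) + 1L
    }
  }

  # qualities: haplotype bases are "true"; any injected change is an "error"
  q <- spec$quality
  is_err <- base != true_base
  qual <- rep.int(as.integer(q$true_q), B)
  if (any(is_err)) {
    hi <- stats::runif(sum(is_err)) < q$error_hi_frac
    qual[is_err] <- ifelse(hi, as.integer(q$error_hi_q),
                           as.integer(q$error_q))
  }

  mapq <- spec$mapq$values[sample.int(length(spec$mapq$values), n,
                                      replace = TRUE, prob = spec$mapq$probs)]
  nm <- as.integer(rowsum(as.numeric(base != ref_code[pos]), ridx))

  base_chr <- utf8ToInt("ACGT")[base]
  qual_chr <- qual + 33L
  ends <- cumsum(len)
  starts_flat <- ends - len + 1L
  seqs <- vapply(seq_len(n),
                 function(i) intToUtf8(base_chr[starts_flat[i]:ends[i]]),
                 character(1))
  quals <- vapply(seq_len(n),
                  function(i) intToUtf8(qual_chr[starts_flat[i]:ends[i]]),
                  character(1))

  reads <- data.frame(
    id = sprintf("read%06d", seq_len(n)),
    start = as.integer(start),
    end = as.integer(start + len - 1L),
    seq = seqs, qual = quals,
    mapq = as.integer(mapq), nm = nm,
    stringsAsFactors = FALSE
  )
  truth <- list(
    haplotype_freqs = as.numeric(freqs),
    haplotype_labels = hap_labels(spec$haplotypes),
    realized_counts = stats::setNames(as.integer(realized),
                                      c("WT", hap_labels(spec$haplotypes))),
    background_rates = rate,
    regime = spec$regime,
    seed = spec$seed
  )
  structure(list(reads = reads, truth = truth, reference = spec$reference),
            class = "amplicon_sim")
}

hap_labels <- function(haplotypes) {
  vapply(haplotypes, function(h)
    paste(sprintf("%s>%s", names(h$subs), toupper(unlist(h$subs))),
          collapse = "/"),
    character(1))
}

#' A deterministic alternate base for a reference position
#'
#' Convenience for building simulation haplotypes: returns the next base in
#' A->C->G->T->A order after the reference base at \code{pos}.
#'
#' @param reference nucleotide string.
#' @param pos 1-based position.
#' @return a single alternate base.
#' @export
alt_base <- function(reference, pos) {
  r <- substr(reference, pos, pos)
  BASES[(match(toupper(r), BASES) %% 4L) + 1L]
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("Simulated amplicon dataset: %d reads, reference %d bp, regime %s\n",
              nrow(x$reads), nchar(x$reference), x$truth$regime))
  cnt <- x$truth$realized_counts
  cat("  realized haplotype counts:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a simulation truth record (JSON)
#'
#' The truth file round-trips losslessly: realized counts, specified
#' frequencies, the background rate matrix and the seed are restored exactly.
#'
#' @param truth the \code{truth} element of an [simulate_amplicon()] result.
#' @param path output JSON path.
#' @return \code{write_sim_truth}: the path, invisibly;
#'   \code{read_sim_truth}: the truth list.
#' @export
write_sim_truth <- function(truth, path) {
  out <- truth
  out$realized_counts <- as.list(truth$realized_counts)  # keep names in JSON
  out$background_rates <- list(
    nrow = nrow(truth$background_rates),
    values = as.numeric(truth$background_rates)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$background_rates <- matrix(x$background_rates$values,
                               nrow = x$background_rates$nrow, ncol = 3L)
  x$haplotype_freqs <- as.numeric(x$haplotype_freqs)
  x$realized_counts <- stats::setNames(as.integer(x$realized_counts),
                                       names(x$realized_counts))
  x$seed <- as.integer(x$seed)
  x
}
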