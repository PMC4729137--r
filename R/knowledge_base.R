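kb_path <- function(file) {
  p <- system.file("extdata", file, package = "ampvar")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' The published cfDNA haplotype table
#'
#' Loads the transcribed per-sample haplotype rows of the CRPC cfDNA cohort:
#' mutant, wild-type and total read counts with the percent-mutant column,
#' one row per haplotype per sample (so a sample with multiple haplotypes
#' occupies several rows, and the same haplotype can recur across a
#' patient's time points). \code{wga2} marks libraries sequenced from
#' whole-genome-amplified DNA.
#'
#' @return data.frame: \code{sample}, \code{patient}, \code{haplotype},
#'   \code{mutant_reads}, \code{wildtype_reads}, \code{total_reads},
#'   \code{percent_mutant}, \code{wga2}.
#' @export
ar_cfdna_haplotypes <- function() {
  utils::read.csv(kb_path("ar_cfdna_haplotypes.csv"),
                  stringsAsFactors = FALSE)
}

#' Cohort summary counts from a haplotype table
#'
#' @param x a haplotype table in the layout of [ar_cfdna_haplotypes()].
#' @return list: \code{n_rows}; \code{n_patients} (distinct patients);
#'   \code{substitutions} and \code{n_substitutions} (distinct single
#'   amino-acid substitutions across all haplotypes); \code{n_patients_with}
#'   — a function mapping a haplotype label to the number of distinct
#'   patients with at least one supporting read for exactly that haplotype.
#' @examples
#' s <- summarize_cohort(ar_cfdna_haplotypes())
#' s$n_patients
#' s$n_patients_with("H875Y")
#' @export
summarize_cohort <- function(x) {
  subs <- unique(unlist(strsplit(x$haplotype, "/", fixed = TRUE)))
  list(
    n_rows = nrow(x),
    n_patients = length(unique(x$patient)),
    substitutions = sort(subs),
    n_substitutions = length(subs),
    n_patients_with = function(label)
      length(unique(x$patient[x$haplotype == label & x$mutant_reads > 0]))
  )
}

parse_potency_cell <- function(cell) {
  censored <- grepl("^>", cell)
  value <- as.numeric(sub("^>", "", cell))
  data.frame(value = value, censored = censored)
}

#' The mutant-by-drug response knowledge base
#'
#' Loads the packaged functional profiles of the wild-type receptor and the
#' 24 CRPC-associated mutants:
#' \itemize{
#'   \item \code{potency}: half-max potencies in long form — the IC50 of the
#'     BF3 inhibitor VPC-13566 (uM) and the EC50s of activation by DHT,
#'     estradiol, progesterone and hydrocortisone (nM). Censored cells
#'     (printed "> 500 nM": no or very weak activation up to the highest
#'     tested steroid concentration) carry \code{censored = TRUE} with the
#'     bound in \code{value}.
#'   \item \code{agonist}: the agonist-conversion class (\code{Yes},
#'     \code{Partial}, \code{No}) of four clinical antagonists
#'     (hydroxyflutamide, bicalutamide, enzalutamide, ARN509) per mutant.
#'     The wild-type row is derived from the study's text rather than its
#'     summary table (\code{source = "text"}).
#' }
#'
#' @return list of class \code{"ar_knowledge_base"} with data.frames
#'   \code{potency} (\code{construct}, \code{drug}, \code{value},
#'   \code{censored}, \code{unit}) and \code{agonist} (\code{construct},
#'   \code{drug}, \code{agonist_class}, \code{source}), plus
#'   \code{constructs}.
#' @export
ar_knowledge_base <- function() {
  pot_wide <- utils::read.csv(kb_path("ar_drug_potency.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  ago_wide <- utils::read.csv(kb_path("ar_agonist_response.csv"),
                              stringsAsFactors = FALSE)
  drugs <- c(vpc13566_ic50_uM = "VPC-13566", dht_ec50_nM = "DHT",
             estradiol_ec50_nM = "estradiol",
             progesterone_ec50_nM = "progesterone",
             hydrocortisone_ec50_nM = "hydrocortisone")
  units <- c(vpc13566_ic50_uM = "uM", dht_ec50_nM = "nM",
             estradiol_ec50_nM = "nM", progesterone_ec50_nM = "nM",
             hydrocortisone_ec50_nM = "nM")
  potency <- do.call(rbind, lapply(names(drugs), function(col) {
    cell <- parse_potency_cell(pot_wide[[col]])
    data.frame(construct = pot_wide$construct, drug = drugs[[col]],
               value = cell$value, censored = cell$censored,
               unit = units[[col]], stringsAsFactors = FALSE)
  }))
  antagonists <- c(hydroxyflutamide = "hydroxyflutamide",
                   bicalutamide = "bicalutamide",
                   enzalutamide = "enzalutamide",
                   arn509 = "ARN509")
  agonist <- do.call(rbind, lapply(names(antagonists), function(col) {
    data.frame(construct = ago_wide$construct, drug = antagonists[[col]],
               agonist_class = ago_wide[[col]], source = ago_wide$source,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(agonist$agonist_class %in% c("Yes", "Partial", "No")))
  structure(list(potency = potency, agonist = agonist,
                 constructs = pot_wide$construct),
            class = "ar_knowledge_base")
}

#' @export
print.ar_knowledge_base <- function(x, ...) {
  cat(sprintf(
    "AR mutant response knowledge base: %d constructs, %d potency entries, %d agonist classes\n",
    length(x$constructs), nrow(x$potency), nrow(x$agonist)))
  invisible(x)
}

#' Map detected mutants to drug-response profiles
#'
#' Looks each queried mutant label up in the packaged knowledge base and
#' reports its agonist-conversion class per antagonist and its half-max
#' potency entries. Drugs whose agonist class is \code{"No"} for every known
#' queried mutant are flagged as retained-antagonist options — antagonists
#' that no detected mutation converts into an agonist, and therefore remain
#' candidate therapies (including older drugs). Unknown labels produce
#' explicit no-profile records, never a guess; lookups never interpolate
#' between mutants.
#'
#' @param mutants character vector of mutant labels (e.g. \code{"T878A"},
#'   \code{"F877L/T878A"}).
#' @param kb a knowledge base from [ar_knowledge_base()].
#' @return a list of class \code{"therapy_profile"}: \code{agonist} and
#'   \code{potency} records for the known mutants, \code{unknown} labels,
#'   and \code{retained_antagonists}.
#' @examples
#' p <- lookup_profile(c("F877L", "W742L"))
#' p$retained_antagonists
#' @export
lookup_profile <- function(mutants, kb = ar_knowledge_base()) {
  mutants <- unique(mutants)
  known <- mutants[mutants %in% kb$constructs]
  unknown <- setdiff(mutants, known)
  agonist <- kb$agonist[kb$agonist$construct %in% known, , drop = FALSE]
  potency <- kb$potency[kb$potency$construct %in% known, , drop = FALSE]
  retained <- if (length(known)) {
    stats::aggregate(agonist_class ~ drug, data = agonist,
                     FUN = function(v) all(v == "No"))
  } else NULL
  structure(list(
    mutants = mutants,
    agonist = agonist, potency = potency, unknown = unknown,
    retained_antagonists =
      if (!is.null(retained)) sort(retained$drug[retained$agonist_class])
      else character()
  ), class = "therapy_profile")
}

#' @export
print.therapy_profile <- function(x, ...) {
  cat("Therapy profile for:", paste(x$mutants, collapse = ", "), "\n")
  if (length(x$unknown))
    cat("  no profile available for:", paste(x$unknown, collapse = ", "), "\n")
  if (nrow(x$agonist)) {
    w <- stats::reshape(x$agonist[, c("construct", "drug", "agonist_class")],
                        idvar = "construct", timevar = "drug",
                        direction = "wide")
    names(w) <- sub("^agonist_class\\.", "", names(w))
    print(w, row.names = FALSE)
  }
  cat("  retained-antagonist options:",
      if (length(x$retained_antagonists))
        paste(x$retained_antagonists, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
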