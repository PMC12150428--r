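#' Default rate parameters for the gene expression model
#'
#' Baseline single-cell gene expression rates, all in 1/min: transcription
#' \code{k_r = 2}, nuclear export \code{k_t = 0.083}, translation
#' \code{k_p = 0.5}, mRNA decay \code{gamma_r = 0.05} (same constant in
#' nucleus and cytosol) and protein decay \code{gamma_p = 0.25}. The
#' two-state switching rates \code{k_on} and \code{k_off} default to
#' 0.2/min and are only used by [twoStateModel()].
#'
#' @param twoState if TRUE, include the gene switching rates.
#' @return named numeric vector of rates (1/min).
#' @examples
#' defaultParameters()
#' @export
defaultParameters <- function(twoState = FALSE) {
  p <- c(k_r = 2, k_t = 0.083, k_p = 0.5, gamma_r = 0.05, gamma_p = 0.25)
  if (twoState) p <- c(p, k_on = 0.2, k_off = 0.2)
  p
}

checkParams <- function(params, required) {
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("parameters must be a named numeric vector")
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("missing rate parameter(s): ", paste(missing, collapse = ", "))
  bad <- !is.finite(params) | params <= 0
  if (any(bad))
    stop("invalid (nonpositive or non-finite) rate parameter(s): ",
         paste(names(params)[bad], collapse = ", "))
  invisible(params)
}

#' Constitutive (always-on gene) expression network
#'
#' Three species (nuclear mRNA \code{Rn}, cytosolic mRNA \code{Rc},
#' protein \code{P}) and six reactions: constitutive transcription
#' (rate \code{k_r}), nuclear export (\code{k_t * Rn}), translation
#' (\code{k_p * Rc}, catalytic in Rc), nuclear and cytosolic mRNA decay
#' (\code{gamma_r} each) and protein decay (\code{gamma_p * P}).
#'
#' @param params named numeric vector of positive rates; see
#'   [defaultParameters()].
#' @return a \linkS4class{ReactionNetwork}.
#' @examples
#' net <- constitutiveModel(defaultParameters())
#' stoichiometry(net)
#' propensities(net, c(Rn = 10, Rc = 5, P = 3))
#' @export
constitutiveModel <- function(params = defaultParameters()) {
  checkParams(params, c("k_r", "k_t", "k_p", "gamma_r", "gamma_p"))
  species <- c("Rn", "Rc", "P")
  S <- cbind(r1 = c(1L, 0L, 0L),   # 0 -> Rn
             r2 = c(-1L, 1L, 0L),  # Rn -> Rc
             r3 = c(0L, 0L, 1L),   # Rc -> Rc + P
             r4 = c(-1L, 0L, 0L),  # Rn -> 0
             r5 = c(0L, -1L, 0L),  # Rc -> 0
             r6 = c(0L, 0L, -1L))  # P -> 0
  rownames(S) <- species
  O <- cbind(r1 = c(0L, 0L, 0L), r2 = c(1L, 0L, 0L), r3 = c(0L, 1L, 0L),
             r4 = c(1L, 0L, 0L), r5 = c(0L, 1L, 0L), r6 = c(0L, 0L, 1L))
  rownames(O) <- species
  new("ReactionNetwork", species = species, stoich = S,
      rateNames = c("k_r", "k_t", "k_p", "gamma_r", "gamma_r", "gamma_p"),
      orders = O,
      params = params[c("k_r", "k_t", "k_p", "gamma_r", "gamma_p")],
      drugTarget = "k_t")
}

#' Bursty two-state expression network
#'
#' Extends the constitutive model with a gene toggling between inactive
#' (\code{Goff}) and active (\code{Gon}) states at rates \code{k_on} and
#' \code{k_off}; transcription fires at \code{k_r * Gon} so it stops when
#' the gene is off. The gene copy number is conserved
#' (\code{Goff + Gon = 1} for the usual single-allele initial state).
#'
#' @param params named numeric vector including \code{k_on} and
#'   \code{k_off}; see [defaultParameters()].
#' @return a \linkS4class{ReactionNetwork} with species
#'   \code{Goff, Gon, Rn, Rc, P}.
#' @examples
#' net <- twoStateModel(defaultParameters(twoState = TRUE))
#' propensities(net, c(Goff = 1, Gon = 0, Rn = 0, Rc = 0, P = 0))
#' @export
twoStateModel <- function(params = defaultParameters(twoState = TRUE)) {
  checkParams(params,
              c("k_r", "k_t", "k_p", "gamma_r", "gamma_p", "k_on", "k_off"))
  species <- c("Goff", "Gon", "Rn", "Rc", "P")
  S <- cbind(r1 = c(-1L, 1L, 0L, 0L, 0L),  # Goff -> Gon
             r2 = c(1L, -1L, 0L, 0L, 0L),  # Gon -> Goff
             r3 = c(0L, 0L, 1L, 0L, 0L),   # Gon: 0 -> Rn
             r4 = c(0L, 0L, -1L, 1L, 0L),  # Rn -> Rc
             r5 = c(0L, 0L, 0L, 0L, 1L),   # Rc -> Rc + P
             r6 = c(0L, 0L, -1L, 0L, 0L),  # Rn -> 0
             r7 = c(0L, 0L, 0L, -1L, 0L),  # Rc -> 0
             r8 = c(0L, 0L, 0L, 0L, -1L))  # P -> 0
  rownames(S) <- species
  O <- matrix(0L, 5, 8, dimnames = list(species, colnames(S)))
  O["Goff", 1] <- 1L; O["Gon", 2] <- 1L; O["Gon", 3] <- 1L
  O["Rn", 4] <- 1L; O["Rc", 5] <- 1L; O["Rn", 6] <- 1L
  O["Rc", 7] <- 1L; O["P", 8] <- 1L
  new("ReactionNetwork", species = species, stoich = S,
      rateNames = c("k_on", "k_off", "k_r", "k_t", "k_p",
                    "gamma_r", "gamma_r", "gamma_p"),
      orders = O,
      params = params[c("k_r", "k_t", "k_p", "gamma_r", "gamma_p",
                        "k_on", "k_off")],
      drugTarget = "k_t")
}

#' Construct a drug schedule
#'
#' @param tDrug application time (min, >= 0).
#' @param efficacy fraction of the export rate removed, in [0, 1]; 0.9
#'   means a 90\%-effective drug leaving 10\% of the baseline rate.
#' @return a \linkS4class{DrugSchedule}.
#' @examples
#' sch <- drugSchedule(tDrug = 120, efficacy = 0.9)
#' effectiveRate(0.083, 130, sch)  # 0.0083
#' @export
drugSchedule <- function(tDrug = 120, efficacy = 0.9) {
  new("DrugSchedule", tDrug = as.numeric(tDrug),
      efficacy = as.numeric(efficacy))
}

#' Export rate under a drug schedule
#'
#' Step modulation of a rate constant: returns \code{k} unchanged for
#' \code{t < tDrug} and \code{(1 - efficacy) * k} for \code{t >= tDrug}
#' (right-continuous, constant thereafter).
#'
#' @param k baseline rate (1/min).
#' @param t time (min); vectorized.
#' @param schedule a \linkS4class{DrugSchedule}, or NULL for no drug.
#' @return modulated rate(s), same length as \code{t}.
#' @export
effectiveRate <- function(k, t, schedule = NULL) {
  if (is.null(schedule)) return(rep_len(k, length(t)))
  stopifnot(is(schedule, "DrugSchedule"))
  ifelse(t >= schedule@tDrug, (1 - schedule@efficacy) * k, k)
}

#' Evaluate mass-action propensities
#'
#' Returns the length-M vector of reaction propensities
#' \eqn{w_\mu(x, t)} at state \code{x} and time \code{t}, applying the law
#' of mass action with combinatorial reactant counting (a second-order
#' requirement on one species contributes \eqn{x(x-1)/2}). If a drug
#' schedule is supplied, the network's target rate (here the export rate
#' \code{k_t}) is modulated per [effectiveRate()].
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param x nonnegative state vector (length = number of species).
#' @param t time (min), used only by the drug schedule.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @return named nonnegative numeric vector, one propensity per reaction.
#' @export
propensities <- function(net, x, t = 0, schedule = NULL) {
  stopifnot(is(net, "ReactionNetwork"))
  if (length(x) != length(net@species))
    stop("state vector must have ", length(net@species), " entries")
  if (any(!is.finite(x)) || any(x < 0))
    stop("state counts must be nonnegative and finite")
  rates <- net@params[net@rateNames]
  if (!is.null(schedule)) {
    isTarget <- net@rateNames == net@drugTarget
    rates[isTarget] <- effectiveRate(rates[isTarget][1], t, schedule)
  }
  w <- rates
  for (mu in seq_along(w)) {
    o <- net@orders[, mu]
    nz <- which(o > 0L)
    for (i in nz) w[mu] <- w[mu] * choose(x[i], o[i])
  }
  w <- pmax(as.numeric(w), 0)
  names(w) <- colnames(net@stoich)
  w
}

#' @describeIn stoichiometry stoichiometry matrix of a reaction network
#' @export
setMethod("stoichiometry", "ReactionNetwork", function(object) object@stoich)

#' @describeIn speciesNames species of a reaction network
#' @export
setMethod("speciesNames", "ReactionNetwork", function(object) object@species)

#' @describeIn parameters rate constants of a reaction network
#' @export
setMethod("parameters", "ReactionNetwork", function(object) object@params)

setMethod("show", "ReactionNetwork", function(object) {
  cat("ReactionNetwork with", length(object@species), "species and",
      ncol(object@stoich), "reactions\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  rates:",
      paste(sprintf("%s=%g", names(object@params), object@params),
            collapse = ", "), "/min\n")
  cat("  drug target:", object@drugTarget, "\n")
})

setMethod("show", "DrugSchedule", function(object) {
  cat(sprintf(
    "DrugSchedule: %.0f%%-effective export inhibition at t = %g min\n",
    100 * object@efficacy, object@tDrug))
})

#' Write a model configuration file
#'
#' Serializes a network's parameters and a drug schedule to a structured
#' key: value text file (YAML, one section per model) using the canonical
#' parameter names \code{k_r, k_t, k_p, gamma_r, gamma_p, k_on, k_off,
#' t_drug, efficacy}.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param file output path.
#' @param schedule optional \linkS4class{DrugSchedule}.
#' @return \code{file}, invisibly.
#' @export
writeModelConfig <- function(net, file, schedule = NULL) {
  model <- if ("k_on" %in% names(net@params)) "two_state" else "constitutive"
  cfg <- list()
  cfg[[model]] <- as.list(net@params)
  if (!is.null(schedule))
    cfg$drug <- list(t_drug = schedule@tDrug, efficacy = schedule@efficacy)
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Read a model configuration file
#'
#' @param file path to a config written by [writeModelConfig()].
#' @return list with elements \code{net} (\linkS4class{ReactionNetwork})
#'   and \code{schedule} (\linkS4class{DrugSchedule} or NULL).
#' @export
readModelConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  sect <- intersect(c("constitutive", "two_state"), names(cfg))
  if (!length(sect))
    stop("config must contain a 'constitutive' or 'two_state' section")
  params <- unlist(cfg[[sect[1]]])
  net <- if (sect[1] == "two_state") twoStateModel(params)
         else constitutiveModel(params)
  schedule <- NULL
  if (!is.null(cfg$drug))
    schedule <- drugSchedule(cfg$drug$t_drug, cfg$drug$efficacy)
  list(net = net, schedule = schedule)
}
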