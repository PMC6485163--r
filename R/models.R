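#' @useDynLib ghostabc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rmultinom rpois quantile cor ks.test sd
#'   setNames
#' @importFrom utils head tail read.table write.table modifyList
NULL

## Population labels ---------------------------------------------------------

#' Panel and ghost population labels
#'
#' The seven-genome analysis panel in its canonical axis order
#' (Altai Neanderthal, Denisovan, East Asian, European, West African,
#' Mbuti, Khoisan), and the full label set including unsampled "ghost"
#' lineages: `NI`/`DI` (the introgressing Neanderthal-like and
#' Denisovan-like populations), `Xe` (deep archaic ghost contributing to
#' Denisovans), `XAf` (basal modern-human ghost) and `Xn`
#' (Neanderthal-lineage ghost). `Chimp` is an outgroup label used only for
#' polarization in the descriptive statistics; it never receives migrants.
#'
#' @return Character vector of labels.
#' @export
panel_populations <- function() c("N", "D", "EAs", "Eu", "WAf", "Mbt", "Kho")

#' @rdname panel_populations
#' @export
all_population_labels <- function() {
  c(panel_populations(), "NI", "DI", "Xe", "XAf", "Xn", "Chimp")
}

#' Demographic model identifiers
#' @return Character vector `c("A","B","C","D","E","F")`.
#' @export
ghost_model_ids <- function() c("A", "B", "C", "D", "E", "F")

## Parameter enumeration -----------------------------------------------------

# Which ghost blocks each model carries.
#  xaf  : basal modern-human ghost (XAf), splits from the AMH stem
#  xn_c : Neanderthal-lineage ghost, splits from the N lineage after the N-D
#         split (rootward of the N/NI split)
#  xn_d : Neanderthal-lineage ghost placed on the archaic stem before the
#         N-D split
model_ghosts <- function(model_id) {
  switch(model_id,
    A = character(0),
    B = "xaf",
    C = "xn_c",
    D = "xn_d",
    E = c("xaf", "xn_c"),
    F = c("xaf", "xn_d"),
    stop("unknown model_id: ", model_id)
  )
}

assert_model_id <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1L ||
      !(model_id %in% ghost_model_ids())) {
    stop("unknown model_id: ", paste(model_id, collapse = ","))
  }
  model_id
}

#' Enumerate the free parameters of a demographic model
#'
#' Returns the named free parameters of one of the six models in a stable,
#' documented order: split times, then pulse proportions, then pulse times,
#' then recent migration rates, then per-branch effective sizes. Model B
#' exposes exactly 52 free parameters; model A 43; models C and D 52;
#' models E and F 61.
#'
#' @param model_id One of `"A"`..`"F"`.
#' @return Character vector of parameter names.
#' @export
enumerate_parameters <- function(model_id) {
  assert_model_id(model_id)
  g <- model_ghosts(model_id)

  times <- c("tEAs_Eu", "tOOA", "tMbt", "tAMH")
  if ("xaf" %in% g) times <- c(times, "tAMH-XAf")
  times <- c(times, "tN_NI", "tD_DI", "tN_D")
  if (any(c("xn_c", "xn_d") %in% g)) times <- c(times, "tXn")
  times <- c(times, "tAMH-Archaics", "tXe")

  pulse_tags <- c("NI_Eurasia", "DI_Han", "EarlyHumans_Neanderthal",
                  "Xe_Denisova")
  if ("xaf" %in% g) {
    pulse_tags <- c(pulse_tags, "Xf_Kho", "Xf_Mbuti", "Xf_WestAfrica")
  }
  if (any(c("xn_c", "xn_d") %in% g)) {
    pulse_tags <- c(pulse_tags, "Xn_Kho", "Xn_Mbuti", "Xn_WestAfrica")
  }
  props  <- paste0("Introgression", pulse_tags)
  ptimes <- paste0("tIntrogression", pulse_tags)

  migr <- c("mEu_WAf", "mEu_Mbt", "mEu_Kho", "mWAf_Mbt", "mWAf_Kho",
            "mMbt_WAf", "mMbt_Kho", "mKho_Mbt")

  sizes <- c("NeEAs", "NeEu", "NeWAf", "NeMbt", "NeKho",
             "NeN", "NeNI", "NeD", "NeDI", "NeXe")
  if ("xaf" %in% g) sizes <- c(sizes, "NeXAf")
  if (any(c("xn_c", "xn_d") %in% g)) sizes <- c(sizes, "NeXn")
  sizes <- c(sizes, "NeAncEAsEu", "NeAncOOA", "NeAncAfr", "NeAncAMH")
  if ("xaf" %in% g) sizes <- c(sizes, "NeAncAMHXAf")
  sizes <- c(sizes, "NeAncN", "NeAncD")
  if ("xn_c" %in% g) sizes <- c(sizes, "NeAncNXn")
  sizes <- c(sizes, "NeAncArchaic")
  if ("xn_d" %in% g) sizes <- c(sizes, "NeAncArcXn")
  sizes <- c(sizes, "NeAncRoot")

  c(times, props, ptimes, migr, sizes)
}

## Priors --------------------------------------------------------------------

#' Default prior specification for a model
#'
#' Shipped default priors for each free parameter: uniform for times (kya)
#' and pulse proportions, log-uniform for effective sizes (diploid) and
#' recent migration rates (per lineage per generation). The supplementary
#' ranges used in the original study are not available, so these defaults
#' are reconstructions: wide boxes chosen to contain the published
#' posterior 95\% credible intervals of model B while keeping the
#' topological ordering constraints satisfiable with high probability.
#'
#' @param model_id One of `"A"`..`"F"`.
#' @return `data.frame` with columns `parameter`, `family`
#'   (`"uniform"`/`"log-uniform"`), `lower`, `upper`, `units`.
#' @export
default_priors <- function(model_id) {
  assert_model_id(model_id)
  pars <- enumerate_parameters(model_id)
  g <- model_ghosts(model_id)

  fam <- rep("uniform", length(pars))
  lo  <- numeric(length(pars))
  hi  <- numeric(length(pars))
  un  <- rep("", length(pars))
  names(fam) <- names(lo) <- names(hi) <- names(un) <- pars

  set_u <- function(p, a, b, unit = "kya") {
    lo[p] <<- a; hi[p] <<- b; un[p] <<- unit
  }
  set_lu <- function(p, a, b, unit) {
    fam[p] <<- "log-uniform"; lo[p] <<- a; hi[p] <<- b; un[p] <<- unit
  }

  set_u("tEAs_Eu", 20, 45)
  set_u("tOOA", 50, 100)
  set_u("tMbt", 60, 160)
  set_u("tAMH", 100, 300)
  if ("xaf" %in% g) set_u("tAMH-XAf", 150, 800)
  set_u("tN_NI", 130, 290)
  set_u("tD_DI", 80, 300)
  set_u("tN_D", 300, 650)
  if ("xn_c" %in% g) set_u("tXn", 150, 290)
  if ("xn_d" %in% g) set_u("tXn", 350, 700)
  set_u("tAMH-Archaics", 300, 1000)
  set_u("tXe", 700, 1500)

  for (p in grep("^Introgression", pars, value = TRUE)) {
    set_u(p, 0, 0.1, "proportion")
  }
  set_u("tIntrogressionNI_Eurasia", 45, 50)
  set_u("tIntrogressionDI_Han", 2, 18)
  set_u("tIntrogressionEarlyHumans_Neanderthal", 305, 395)
  set_u("tIntrogressionXe_Denisova", 72, 78)
  for (tag in c("Xf", "Xn")) {
    pk <- paste0("tIntrogression", tag, "_Kho")
    pm <- paste0("tIntrogression", tag, "_Mbuti")
    pw <- paste0("tIntrogression", tag, "_WestAfrica")
    if (pk %in% pars) set_u(pk, 5, 95)
    if (pm %in% pars) set_u(pm, 5, 55)
    if (pw %in% pars) set_u(pw, 5, 35)
  }

  for (p in grep("^m", pars, value = TRUE)) {
    set_lu(p, 1e-6, 1e-3, "per generation")
  }

  modern <- c("NeEAs", "NeEu", "NeWAf", "NeMbt", "NeKho")
  archaic <- intersect(c("NeN", "NeNI", "NeD", "NeDI", "NeXe", "NeXAf",
                         "NeXn"), pars)
  anc <- grep("^NeAnc", pars, value = TRUE)
  for (p in modern)  set_lu(p, 3000, 50000, "diploid")
  for (p in archaic) set_lu(p, 500, 20000, "diploid")
  for (p in anc)     set_lu(p, 2000, 40000, "diploid")

  data.frame(parameter = pars, family = unname(fam[pars]),
             lower = unname(lo[pars]), upper = unname(hi[pars]),
             units = unname(un[pars]), stringsAsFactors = FALSE)
}

## Topological validity ------------------------------------------------------

# Check ordering constraints of a named parameter vector for a model.
# Returns TRUE, or a character message naming the violated constraint.
check_topology <- function(model_id, params) {
  g <- model_ghosts(model_id)
  p <- function(nm) unname(params[[nm]])

  chain <- c("tEAs_Eu", "tOOA", "tMbt", "tAMH")
  if ("xaf" %in% g) chain <- c(chain, "tAMH-XAf")
  chain <- c(chain, "tAMH-Archaics", "tXe")
  v <- vapply(chain, p, numeric(1))
  if (any(diff(v) <= 0)) {
    i <- which(diff(v) <= 0)[1]
    return(sprintf("ordering violation: %s >= %s", chain[i], chain[i + 1]))
  }
  if (p("tN_NI") >= p("tN_D")) return("ordering violation: tN_NI >= tN_D")
  if (p("tD_DI") >= p("tN_D")) return("ordering violation: tD_DI >= tN_D")
  if (p("tN_D") >= p("tAMH-Archaics")) {
    return("ordering violation: tN_D >= tAMH-Archaics")
  }
  if ("xn_c" %in% g) {
    if (!(p("tXn") > p("tN_NI") && p("tXn") < p("tN_D"))) {
      return("ordering violation: tXn outside (tN_NI, tN_D)")
    }
  }
  if ("xn_d" %in% g) {
    if (!(p("tXn") > p("tN_D") && p("tXn") < p("tAMH-Archaics"))) {
      return("ordering violation: tXn outside (tN_D, tAMH-Archaics)")
    }
  }

  win <- function(nm, a, b) {
    t <- p(nm)
    if (!(t > a && t < b)) {
      return(sprintf("pulse time violation: %s outside (%.6g, %.6g)", nm, a, b))
    }
    TRUE
  }
  checks <- list(
    win("tIntrogressionNI_Eurasia", p("tEAs_Eu"), p("tOOA")),
    win("tIntrogressionDI_Han", 0, p("tEAs_Eu")),
    win("tIntrogressionEarlyHumans_Neanderthal", p("tAMH"),
        min(p("tN_D"), p("tAMH-Archaics"))),
    win("tIntrogressionXe_Denisova", 0, p("tD_DI"))
  )
  for (tag in c("Xf", "Xn")) {
    if (paste0("tIntrogression", tag, "_Kho") %in% names(params)) {
      checks <- c(checks, list(
        win(paste0("tIntrogression", tag, "_Kho"), 0, p("tAMH")),
        win(paste0("tIntrogression", tag, "_Mbuti"), 0, p("tMbt")),
        win(paste0("tIntrogression", tag, "_WestAfrica"), 0, p("tOOA"))
      ))
    }
  }
  bad <- checks[vapply(checks, is.character, logical(1))]
  if (length(bad)) return(bad[[1]])
  TRUE
}

## Drawing from priors -------------------------------------------------------

draw_one <- function(priors) {
  u <- runif(nrow(priors))
  ifelse(priors$family == "log-uniform",
         exp(log(priors$lower) + u * (log(priors$upper) - log(priors$lower))),
         priors$lower + u * (priors$upper - priors$lower))
}

#' Draw parameter vectors from the prior
#'
#' Samples each parameter independently from its prior, then
#' rejection-resamples whole vectors until the topological ordering
#' constraints of the model are satisfied (at most `max_attempts` tries per
#' vector). Draws are reproducible under [set.seed()].
#'
#' @param model_id One of `"A"`..`"F"`.
#' @param n Number of vectors to draw.
#' @param priors Prior specification as returned by [default_priors()].
#' @param max_attempts Maximum rejection attempts per vector.
#' @return For `n = 1` a named numeric vector; otherwise an `n` x p matrix
#'   with parameter names as columns.
#' @export
draw_parameters <- function(model_id, n = 1, priors = default_priors(model_id),
                            max_attempts = 1000) {
  assert_model_id(model_id)
  need <- enumerate_parameters(model_id)
  if (!all(need %in% priors$parameter)) {
    stop("priors do not cover parameters: ",
         paste(setdiff(need, priors$parameter), collapse = ", "))
  }
  priors <- priors[match(need, priors$parameter), ]
  if (any(priors$lower >= priors$upper)) stop("prior with lower >= upper")

  out <- matrix(NA_real_, nrow = n, ncol = length(need),
                dimnames = list(NULL, need))
  for (i in seq_len(n)) {
    ok <- FALSE
    last_msg <- ""
    for (a in seq_len(max_attempts)) {
      x <- draw_one(priors)
      names(x) <- need
      chk <- check_topology(model_id, as.list(x))
      if (isTRUE(chk)) { out[i, ] <- x; ok <- TRUE; break }
      last_msg <- chk
    }
    if (!ok) {
      stop("could not satisfy ordering constraints after ", max_attempts,
           " attempts; last: ", last_msg)
    }
  }
  if (n == 1) out[1, ] else out
}

## Model building ------------------------------------------------------------

internal_branches <- function(model_id) {
  g <- model_ghosts(model_id)
  b <- c("ANC_EAS_EU", "ANC_OOA", "ANC_AFR", "ANC_AMH")
  if ("xaf" %in% g) b <- c(b, "ANC_AMHX")
  b <- c(b, "ANC_N", "ANC_D")
  if ("xn_c" %in% g) b <- c(b, "ANC_NXN")
  b <- c(b, "ANC_ARC")
  if ("xn_d" %in% g) b <- c(b, "ANC_ARCXN")
  c(b, "ROOT")
}

# parameter name -> population name, for effective sizes
size_param_pop <- function() {
  c(NeEAs = "EAs", NeEu = "Eu", NeWAf = "WAf", NeMbt = "Mbt", NeKho = "Kho",
    NeN = "N", NeNI = "NI", NeD = "D", NeDI = "DI", NeXe = "Xe",
    NeXAf = "XAf", NeXn = "Xn",
    NeAncEAsEu = "ANC_EAS_EU", NeAncOOA = "ANC_OOA", NeAncAfr = "ANC_AFR",
    NeAncAMH = "ANC_AMH", NeAncAMHXAf = "ANC_AMHX",
    NeAncN = "ANC_N", NeAncD = "ANC_D", NeAncNXn = "ANC_NXN",
    NeAncArchaic = "ANC_ARC", NeAncArcXn = "ANC_ARCXN", NeAncRoot = "ROOT")
}

#' Build a fully resolved demographic model
#'
#' Resolves one of the six model topologies with a concrete parameter
#' vector into an explicit event list: population splits (rootward merges),
#' instantaneous introgression pulses, and recent continuous migrations.
#' All models share the seven fixed features of the base model (archaic
#' Neanderthal/Denisovan lineages with their introgressing sister
#' populations NI and DI, early-modern-human introgression into
#' Neanderthals, a deep ghost Xe contributing to Denisovans, Khoisan as the
#' earliest modern-human split, the out-of-Africa event, and recent
#' African/European migrations); models B-F add ghost lineages XAf and/or
#' Xn with pulses into the African populations.
#'
#' @param model_id One of `"A"`..`"F"`.
#' @param params Named numeric vector covering
#'   `enumerate_parameters(model_id)` (times in kya).
#' @param generation_time Years per generation used to convert kya to
#'   generations (default 29).
#' @param sample_ages Named vector of sampling ages in kya for the ancient
#'   genomes (defaults: Altai Neanderthal 120, Denisovan 70).
#' @param samples Named integer vector: diploid genomes sampled per panel
#'   population. Defaults to one per member of [panel_populations()].
#' @return An object of class `ghost_model`: list with `model_id`,
#'   `populations` (name, Ne, sample time, diploids sampled), `events`
#'   (kind, time_kya, time_gen, source, dest, magnitude), `migrations`
#'   (from, to, rate; forward-in-time direction), and `generation_time`.
#' @export
build_model <- function(model_id, params, generation_time = 29,
                        sample_ages = c(N = 120, D = 70),
                        samples = NULL) {
  assert_model_id(model_id)
  params <- unlist(params)
  need <- enumerate_parameters(model_id)
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  params <- params[need]
  props <- params[grep("^Introgression", need)]
  if (any(props < 0 | props > 1)) stop("pulse proportion outside [0,1]")
  chk <- check_topology(model_id, as.list(params))
  if (!isTRUE(chk)) stop("topology error: ", chk)

  g <- model_ghosts(model_id)
  p <- function(nm) unname(params[[nm]])

  pops <- c("EAs", "Eu", "WAf", "Mbt", "Kho", "N", "NI", "D", "DI", "Xe")
  if ("xaf" %in% g) pops <- c(pops, "XAf")
  if (any(c("xn_c", "xn_d") %in% g)) pops <- c(pops, "Xn")
  pops <- c(pops, internal_branches(model_id))

  spp <- size_param_pop()
  ne <- vapply(pops, function(q) {
    nm <- names(spp)[match(q, spp)]
    unname(params[[nm]])
  }, numeric(1))

  stime <- setNames(rep(0, length(pops)), pops)
  for (nm in names(sample_ages)) stime[nm] <- sample_ages[[nm]]
  if (is.null(samples)) {
    samples <- setNames(rep(1L, length(panel_populations())),
                        panel_populations())
  }
  ndip <- setNames(rep(0L, length(pops)), pops)
  ndip[names(samples)] <- as.integer(samples)

  ev <- list()
  add_split <- function(child, parent, t) {
    ev[[length(ev) + 1L]] <<- list(kind = "split", time = t, source = child,
                                   dest = parent, magnitude = NA_real_)
  }
  add_pulse <- function(src, dst, t, prop) {
    ev[[length(ev) + 1L]] <<- list(kind = "pulse_introgression", time = t,
                                   source = src, dest = dst, magnitude = prop)
  }

  # modern-human side
  add_split("EAs", "ANC_EAS_EU", p("tEAs_Eu"))
  add_split("Eu", "ANC_EAS_EU", p("tEAs_Eu"))
  add_split("ANC_EAS_EU", "ANC_OOA", p("tOOA"))
  add_split("WAf", "ANC_OOA", p("tOOA"))
  add_split("ANC_OOA", "ANC_AFR", p("tMbt"))
  add_split("Mbt", "ANC_AFR", p("tMbt"))
  add_split("ANC_AFR", "ANC_AMH", p("tAMH"))
  add_split("Kho", "ANC_AMH", p("tAMH"))
  amh_top <- "ANC_AMH"
  if ("xaf" %in% g) {
    add_split("ANC_AMH", "ANC_AMHX", p("tAMH-XAf"))
    add_split("XAf", "ANC_AMHX", p("tAMH-XAf"))
    amh_top <- "ANC_AMHX"
  }

  # archaic side
  add_split("N", "ANC_N", p("tN_NI"))
  add_split("NI", "ANC_N", p("tN_NI"))
  add_split("D", "ANC_D", p("tD_DI"))
  add_split("DI", "ANC_D", p("tD_DI"))
  n_top <- "ANC_N"
  if ("xn_c" %in% g) {
    add_split("ANC_N", "ANC_NXN", p("tXn"))
    add_split("Xn", "ANC_NXN", p("tXn"))
    n_top <- "ANC_NXN"
  }
  add_split(n_top, "ANC_ARC", p("tN_D"))
  add_split("ANC_D", "ANC_ARC", p("tN_D"))
  arc_top <- "ANC_ARC"
  if ("xn_d" %in% g) {
    add_split("ANC_ARC", "ANC_ARCXN", p("tXn"))
    add_split("Xn", "ANC_ARCXN", p("tXn"))
    arc_top <- "ANC_ARCXN"
  }

  add_split(amh_top, "ROOT", p("tAMH-Archaics"))
  add_split(arc_top, "ROOT", p("tAMH-Archaics"))
  add_split("Xe", "ROOT", p("tXe"))

  # pulses; the lineage names are resolved to the branch alive at pulse time
  amh_at <- function(t) {
    if ("xaf" %in% g && t > p("tAMH-XAf")) "ANC_AMHX" else "ANC_AMH"
  }
  nlin_at <- function(t) {
    if (t < p("tN_NI")) "N"
    else if ("xn_c" %in% g && t > p("tXn")) "ANC_NXN"
    else "ANC_N"
  }
  dlin_at <- function(t) if (t < p("tD_DI")) "D" else "ANC_D"

  t1 <- p("tIntrogressionNI_Eurasia")
  add_pulse("NI", "ANC_EAS_EU", t1, p("IntrogressionNI_Eurasia"))
  t2 <- p("tIntrogressionDI_Han")
  add_pulse("DI", "EAs", t2, p("IntrogressionDI_Han"))
  t3 <- p("tIntrogressionEarlyHumans_Neanderthal")
  add_pulse(amh_at(t3), nlin_at(t3), t3,
            p("IntrogressionEarlyHumans_Neanderthal"))
  t4 <- p("tIntrogressionXe_Denisova")
  add_pulse("Xe", dlin_at(t4), t4, p("IntrogressionXe_Denisova"))

  ghost_pulses <- function(tag, src) {
    add_pulse(src, "Kho", p(paste0("tIntrogression", tag, "_Kho")),
              p(paste0("Introgression", tag, "_Kho")))
    add_pulse(src, "Mbt", p(paste0("tIntrogression", tag, "_Mbuti")),
              p(paste0("Introgression", tag, "_Mbuti")))
    add_pulse(src, "WAf", p(paste0("tIntrogression", tag, "_WestAfrica")),
              p(paste0("Introgression", tag, "_WestAfrica")))
  }
  if ("xaf" %in% g) ghost_pulses("Xf", "XAf")
  if (any(c("xn_c", "xn_d") %in% g)) ghost_pulses("Xn", "Xn")

  events <- do.call(rbind, lapply(ev, function(e) {
    data.frame(kind = e$kind, time_kya = e$time, source = e$source,
               dest = e$dest, magnitude = e$magnitude,
               stringsAsFactors = FALSE)
  }))
  events <- events[order(events$time_kya, events$kind != "pulse_introgression"), ]
  rownames(events) <- NULL
  events$time_gen <- events$time_kya * 1000 / generation_time

  migr <- data.frame(
    from = c("Eu", "Eu", "Eu", "WAf", "WAf", "Mbt", "Mbt", "Kho"),
    to   = c("WAf", "Mbt", "Kho", "Mbt", "Kho", "WAf", "Kho", "Mbt"),
    rate = unname(params[c("mEu_WAf", "mEu_Mbt", "mEu_Kho", "mWAf_Mbt",
                           "mWAf_Kho", "mMbt_WAf", "mMbt_Kho", "mKho_Mbt")]),
    stringsAsFactors = FALSE)

  structure(list(
    model_id = model_id,
    populations = data.frame(
      name = pops, Ne = unname(ne), sample_time_kya = unname(stime[pops]),
      n_diploid = unname(ndip[pops]), stringsAsFactors = FALSE),
    events = events,
    migrations = migr,
    generation_time = generation_time,
    params = params
  ), class = "ghost_model")
}

#' @export
print.ghost_model <- function(x, ...) {
  cat("Demographic model", x$model_id, "-", nrow(x$populations),
      "populations,", nrow(x$events), "events,",
      length(x$params), "free parameters\n")
  cat("sampled:", paste(x$populations$name[x$populations$n_diploid > 0],
                        collapse = " "), "\n")
  invisible(x)
}

#' Prior midpoint parameter vector
#'
#' Midpoint of each prior (geometric midpoint for log-uniform priors).
#' Used as the fixed parameter set for the synthetic noise panel.
#'
#' @inheritParams draw_parameters
#' @return Named numeric vector.
#' @export
prior_midpoint <- function(model_id, priors = default_priors(model_id)) {
  x <- ifelse(priors$family == "log-uniform",
              exp((log(priors$lower) + log(priors$upper)) / 2),
              (priors$lower + priors$upper) / 2)
  setNames(x, priors$parameter)
}
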