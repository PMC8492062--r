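#' Euclidean distance between two neurons
#'
#' Neurons are point-like but carry (x, y) coordinates in arbitrary distance
#' units (a.d.u.): x runs rostrocaudally (one model somite = 1.6 a.d.u.) and
#' y = +1 / -1 marks the right / left side.
#'
#' @param x1,y1,x2,y2 coordinates (vectorized).
#' @return distance in a.d.u.
#' @export
euclidean_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Axonal conduction delay from distance
#'
#' Delays are distance over conduction speed, \code{delay = D / cv}, with cv in
#' a.d.u. per ms (4.0 single coiling, 1.0 double coiling, 0.8 beat-and-glide).
#'
#' @param distance a.d.u.
#' @param cv conduction speed, a.d.u./ms; must be positive.
#' @return delay in ms.
#' @export
compute_delay <- function(distance, cv) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0)
    stop("conduction speed cv must be a positive number")
  distance / cv
}

# ---- projection rules ------------------------------------------------------

# A rule describes one class of projections from a presynaptic population to a
# postsynaptic population. Modes:
#   kernel         all-to-all within the rostral IC kernel (no self edges)
#   first_n        every pre neuron to the first `desc` chain members
#   neighbor_count `asc` nearest strictly-rostral and `desc` nearest strictly-
#                  caudal members of the target chain (by x)
#   neighbor_total the `desc` nearest members of the target chain by |dx|
#                  (ties resolved rostral-first)
#   segment_range  targets with segment in [seg - asc, seg + desc]
#   all            every member of the target population
proj_rule <- function(name, pre, post, type, weight, mode,
                      asc = 0, desc = 0, include_same = TRUE,
                      contralateral = FALSE, noise_sd = 0) {
  list(name = name, pre = pre, post = post, type = type, weight = weight,
       mode = mode, asc = asc, desc = desc, include_same = include_same,
       contralateral = contralateral, noise_sd = noise_sd)
}

rule_targets <- function(rule, pre_row, post_pop, asc, desc) {
  switch(rule$mode,
    kernel = which(post_pop$index != pre_row$index),
    all = seq_len(nrow(post_pop)),
    pre_first_n = if (pre_row$index <= max(0, round(desc)))
      seq_len(nrow(post_pop)) else integer(0),
    first_n = which(post_pop$index <= max(0, round(desc))),
    neighbor_count = {
      dx <- post_pop$x - pre_row$x
      rost <- which(dx < 0)
      caud <- which(dx > 0)
      rost <- rost[order(-dx[rost])][seq_len(min(length(rost), max(0, round(asc))))]
      caud <- caud[order(dx[caud])][seq_len(min(length(caud), max(0, round(desc))))]
      c(rost, caud)
    },
    neighbor_total = {
      dx <- post_pop$x - pre_row$x
      cand <- which(dx != 0)
      cand <- cand[order(abs(dx[cand]), dx[cand])]
      cand[seq_len(min(length(cand), max(0, round(desc))))]
    },
    segment_range = {
      lo <- pre_row$segment - max(0, round(asc))
      hi <- pre_row$segment + max(0, round(desc))
      idx <- which(post_pop$segment >= lo & post_pop$segment <= hi)
      if (!rule$include_same)
        idx <- idx[post_pop$segment[idx] != pre_row$segment]
      idx
    },
    stop("unknown projection rule mode: ", rule$mode)
  )
}

# Generate the directed edge list of one rule, both body sides. Gap-junction
# rules are symmetrized afterwards. length_factors, when given, is a numeric
# vector over the rule's presynaptic neurons (left side first) scaling the
# rule's rostrocaudal extents, which are then rounded to whole segments.
apply_rule <- function(rule, neurons, length_factors = NULL) {
  pre_all <- neurons[neurons$kind == rule$pre, , drop = FALSE]
  edges <- vector("list", nrow(pre_all))
  pre_order <- order(match(pre_all$side, c("left", "right")), pre_all$index)
  pre_all <- pre_all[pre_order, , drop = FALSE]
  for (i in seq_len(nrow(pre_all))) {
    pre_row <- pre_all[i, ]
    post_side <- if (rule$contralateral) {
      if (pre_row$side == "left") "right" else "left"
    } else pre_row$side
    post_pop <- neurons[neurons$kind == rule$post & neurons$side == post_side, ,
                        drop = FALSE]
    f <- if (is.null(length_factors)) 1 else length_factors[i]
    tgt <- rule_targets(rule, pre_row, post_pop,
                        asc = rule$asc * f, desc = rule$desc * f)
    if (length(tgt) == 0L) next
    edges[[i]] <- data.frame(pre = pre_row$id, post = post_pop$id[tgt],
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) return(NULL)
  edges$kind <- rule$type
  edges$weight <- rule$weight
  edges$rule <- rule$name
  edges
}

symmetrize_gap <- function(edges) {
  rev <- edges
  rev$pre <- edges$post
  rev$post <- edges$pre
  both <- rbind(edges, rev)
  both[!duplicated(both[, c("pre", "post")]), , drop = FALSE]
}

# ---- rule sets per developmental model -------------------------------------

rules_single_coiling <- function(w, cw, n_somites, ic_reach) {
  list(
    proj_rule("gap.IC.IC", "IC", "IC", "gap", w[["IC-IC"]], "kernel"),
    proj_rule("gap.IC.MN", "IC", "MN", "gap", w[["IC-MN"]], "first_n",
              desc = ic_reach),
    proj_rule("gap.IC.V0d", "IC", "V0d", "gap", w[["V0d-IC"]], "first_n",
              desc = 4),
    proj_rule("gap.MN.MN", "MN", "MN", "gap", w[["MN-MN"]], "neighbor_total",
              desc = 3),
    proj_rule("gap.V0d.V0d", "V0d", "V0d", "gap", w[["V0d-V0d"]],
              "neighbor_total", desc = 3),
    proj_rule("gap.MN.V0d", "MN", "V0d", "gap", w[["V0d-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("chem.V0d.MN", "V0d", "MN", "gly", cw[["V0d-MN"]],
              "segment_range", asc = 5, desc = 5, contralateral = TRUE),
    proj_rule("chem.V0d.IC", "V0d", "IC", "gly", cw[["V0d-IC"]], "all",
              contralateral = TRUE)
  )
}

rules_double_coiling <- function(w, cw, n_somites, ic_reach) {
  c(rules_single_coiling(w, cw, n_somites, ic_reach), list(
    proj_rule("gap.V0v.V0v", "V0v", "V0v", "gap", w[["V0v-V0v"]],
              "neighbor_total", desc = 3),
    proj_rule("gap.V0v.MN", "V0v", "MN", "gap", w[["V0v-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("gap.IC.V0v", "IC", "V0v", "gap", w[["V0v-IC"]], "first_n",
              desc = 4),
    proj_rule("gap.V2a.IC", "V2a", "IC", "gap", w[["V2a-IC"]],
              "pre_first_n", desc = 4),
    proj_rule("gap.V2a.MN", "V2a", "MN", "gap", w[["V2a-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("gap.V2a.V2a", "V2a", "V2a", "gap", w[["V2a-V2a"]],
              "neighbor_total", desc = 3),
    proj_rule("chem.V0d.V2a", "V0d", "V2a", "gly", cw[["V0d-V2a"]],
              "segment_range", asc = 5, desc = 5, contralateral = TRUE),
    proj_rule("chem.V0v.IC", "V0v", "IC", "glut", cw[["V0v-IC"]], "all",
              contralateral = TRUE),
    proj_rule("chem.V2a.V0v", "V2a", "V0v", "glut", cw[["V2a-V0v"]],
              "segment_range", asc = 3, desc = 3)
  ))
}

rules_beat_glide <- function(w, cw, n_somites, dI6_noise_sd) {
  list(
    proj_rule("gap.MN.MN", "MN", "MN", "gap", w[["MN-MN"]], "neighbor_total",
              desc = 3),
    proj_rule("gap.dI6.dI6", "dI6", "dI6", "gap", w[["dI6-dI6"]],
              "neighbor_total", desc = 3),
    proj_rule("gap.V0v.V0v", "V0v", "V0v", "gap", w[["V0v-V0v"]],
              "neighbor_total", desc = 3),
    proj_rule("gap.V2a.V2a", "V2a", "V2a", "gap", w[["V2a-V2a"]],
              "neighbor_total", desc = 3),
    proj_rule("gap.dI6.MN", "dI6", "MN", "gap", w[["dI6-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("gap.V0v.MN", "V0v", "MN", "gap", w[["V0v-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("gap.V2a.MN", "V2a", "MN", "gap", w[["V2a-MN"]],
              "neighbor_count", asc = 3, desc = 3),
    proj_rule("chem.dI6.MN", "dI6", "MN", "gly", cw[["dI6-MN"]],
              "segment_range", asc = 1, desc = 3, include_same = FALSE,
              contralateral = TRUE),
    proj_rule("chem.dI6.dI6", "dI6", "dI6", "gly", cw[["dI6-dI6"]],
              "segment_range", asc = 1, desc = 3, include_same = FALSE,
              contralateral = TRUE, noise_sd = dI6_noise_sd),
    proj_rule("chem.dI6.V2a", "dI6", "V2a", "gly", cw[["dI6-V2a"]],
              "segment_range", asc = 1, desc = 3, include_same = FALSE,
              contralateral = TRUE),
    proj_rule("chem.V0v.V2a", "V0v", "V2a", "glut", cw[["V0v-V2a"]],
              "segment_range", asc = 1, desc = 3, include_same = FALSE,
              contralateral = TRUE),
    proj_rule("chem.V2a.MN.desc", "V2a", "MN", "glut", cw[["V2a-MN"]],
              "segment_range", asc = 0, desc = 6, include_same = TRUE),
    proj_rule("chem.V2a.MN.asc", "V2a", "MN", "glut", cw[["V2a-MN"]],
              "segment_range", asc = 2, desc = 0, include_same = FALSE),
    proj_rule("chem.V2a.dI6", "V2a", "dI6", "glut", cw[["V2a-dI6"]],
              "segment_range", asc = 0, desc = 6, include_same = TRUE),
    proj_rule("chem.V2a.V0v.desc", "V2a", "V0v", "glut", cw[["V2a-V0v"]],
              "segment_range", asc = 0, desc = 6, include_same = TRUE),
    proj_rule("chem.V2a.V0v.asc", "V2a", "V0v", "glut", cw[["V2a-V0v"]],
              "segment_range", asc = 2, desc = 0, include_same = FALSE),
    proj_rule("chem.V2a.V2a", "V2a", "V2a", "glut", cw[["V2a-V2a"]],
              "segment_range", asc = 0, desc = 6, include_same = FALSE),
    proj_rule("chem.V2a.V1", "V2a", "V1", "glut", cw[["V2a-V1"]],
              "segment_range", asc = 0, desc = 3, include_same = TRUE),
    proj_rule("chem.V1.MN", "V1", "MN", "gly", cw[["V1-MN"]],
              "segment_range", asc = 2, desc = 0, include_same = TRUE),
    proj_rule("chem.V1.dI6", "V1", "dI6", "gly", cw[["V1-dI6"]],
              "segment_range", asc = 2, desc = 0, include_same = TRUE),
    proj_rule("chem.V1.V0v", "V1", "V0v", "gly", cw[["V1-V0v"]],
              "segment_range", asc = 2, desc = 0, include_same = TRUE),
    proj_rule("chem.V1.V2a", "V1", "V2a", "gly", cw[["V1-V2a"]],
              "segment_range", asc = 2, desc = 0, include_same = TRUE)
  )
}

# ---- generic circuit assembly ----------------------------------------------

build_circuit <- function(variant, n_somites, overrides = NULL,
                          length_factors = NULL) {
  sheet <- apply_overrides(model_param_sheet(variant), overrides)
  cst <- sheet$constants

  pops <- names(sheet$populations)
  neurons <- do.call(rbind, lapply(pops, function(kind) {
    cnt <- if (identical(kind, "IC")) sheet$populations[[kind]]$count
           else n_somites
    rbind(
      make_population_from_sheet(sheet, kind, "left", cnt),
      make_population_from_sheet(sheet, kind, "right", cnt)
    )
  }))
  neurons$id <- seq_len(nrow(neurons))

  # IC axons gap-couple the motoneuron chain along the whole body: with the
  # printed per-pair conductances, chain-to-chain diffusion alone does not
  # recruit the caudal somites, so the rostral kernel's reach is the motor
  # recruitment path (the same lever the longer-bodied variants use).
  # Interneuron chains keep the first-four-somite coupling.
  ic_reach <- n_somites
  rules <- switch(variant,
    single_coiling = rules_single_coiling(sheet$gap_weights,
                                          sheet$chem_weights, n_somites,
                                          ic_reach),
    double_coiling = rules_double_coiling(sheet$gap_weights,
                                          sheet$chem_weights, n_somites,
                                          ic_reach),
    rules_beat_glide(sheet$gap_weights, sheet$chem_weights, n_somites,
                     if (is.null(sheet$dI6_noise_sd)) 0 else sheet$dI6_noise_sd)
  )

  conns <- vector("list", length(rules))
  for (r in seq_along(rules)) {
    rule <- rules[[r]]
    lf <- if (is.null(length_factors)) NULL else length_factors[[rule$name]]
    e <- apply_rule(rule, neurons, lf)
    if (is.null(e)) next
    if (identical(rule$type, "gap")) e <- symmetrize_gap(e)
    if (rule$noise_sd > 0) {
      scale <- pmax(0, stats::rnorm(nrow(e), mean = 1, sd = rule$noise_sd))
      e$weight <- e$weight * scale
    }
    conns[[r]] <- e
  }
  conns <- do.call(rbind, conns)
  rownames(conns) <- NULL

  # Gap-junction pairs are realized by `gap_pair_junctions` junction instances
  # (one formed from each endpoint), so the per-direction conductance is the
  # table weight times that count.
  gpj <- if (is.null(cst$gap_pair_junctions)) 1 else cst$gap_pair_junctions
  isgap <- conns$kind == "gap"
  conns$weight[isgap] <- conns$weight[isgap] * gpj

  conns$distance <- euclidean_distance(neurons$x[conns$pre],
                                       neurons$y[conns$pre],
                                       neurons$x[conns$post],
                                       neurons$y[conns$post])
  conns$delay <- compute_delay(conns$distance, cst$cv)

  mus <- sheet$muscle
  mn <- neurons[neurons$kind == "MN", , drop = FALSE]
  mn <- mn[order(match(mn$side, c("left", "right")), mn$index), , drop = FALSE]
  muscles <- data.frame(
    cell = mn$index, side = mn$side, mn_id = mn$id,
    weight = sheet$chem_weights[["MN-Muscle"]],
    stringsAsFactors = FALSE
  )

  structure(list(
    name = sheet$name, variant = variant, n_somites = n_somites,
    neurons = neurons, connections = conns, muscles = muscles,
    constants = cst, muscle = mus, body = sheet$body,
    rule_info = data.frame(
      name = vapply(rules, `[[`, "", "name"),
      pre = vapply(rules, `[[`, "", "pre"),
      mode = vapply(rules, `[[`, "", "mode"),
      stringsAsFactors = FALSE
    ),
    meta = list(variant = variant, n_somites = n_somites,
                overrides = overrides)
  ), class = "spinal_circuit")
}

make_population_from_sheet <- function(sheet, kind, side, count) {
  pop <- sheet$populations[[kind]]
  n <- seq_len(count) - 1L
  x <- pop$x_offset + pop$x_step * n
  y <- if (side == "right") 1 else -1
  onset <- 0
  if (!is.null(pop$drive_onset)) onset <- pop$drive_onset[[side]]
  seg <- if (identical(kind, "IC")) rep(0L, count)
         else seq_len(count) + segment_offset(kind)
  data.frame(
    kind = kind, side = side, index = seq_len(count), segment = seg,
    x = x, y = y,
    a = pop$a, b = pop$b, c = pop$c, d = pop$d, Vmax = pop$Vmax,
    Vr = pop$Vr, Vt = pop$Vt, k = pop$k, C = pop$C,
    I_drive = if (is.null(pop$I_drive)) 0 else pop$I_drive,
    drive_onset = onset,
    stringsAsFactors = FALSE
  )
}

#' Build the single coiling circuit model
#'
#' A rostral kernel of five recurrently gap-coupled IC pacemakers per side
#' drives ipsilateral chains of motoneurons and commissural inhibitory V0ds
#' through electrical synapses; V0ds send glycinergic projections to
#' contralateral MNs (five segments up and down) and to all contralateral ICs.
#' Only the left ICs receive the tonic command, so coils are generated on one
#' side.
#'
#' @param n_somites 10 (base) or 30.
#' @param overrides named list of dotted-path parameter overrides, see
#'   [apply_overrides()].
#' @return a \code{spinal_circuit} object.
#' @export
#' @examples
#' circ <- build_single_coiling()
#' print(circ)
build_single_coiling <- function(n_somites = 10, overrides = NULL) {
  if (!n_somites %in% c(10, 30))
    stop("single coiling model supports 10 or 30 somites")
  build_circuit("single_coiling", n_somites, overrides)
}

#' Build the double coiling circuit model
#'
#' Extends the coiling scaffold with commissural excitatory V0vs (projecting
#' glutamatergic synapses to all contralateral ICs) and ipsilateral descending
#' V2as (gap-coupled to ICs, glutamatergic onto V0vs). Both sides receive the
#' tonic command; the right side is delayed by 1500 ms.
#'
#' @inheritParams build_single_coiling
#' @export
build_double_coiling <- function(n_somites = 10, overrides = NULL) {
  if (!n_somites %in% c(10, 30))
    stop("double coiling model supports 10 or 30 somites")
  build_circuit("double_coiling", n_somites, overrides)
}

#' Build a beat-and-glide swimming circuit model
#'
#' A 15-somite network with no pacemaker kernel: tonic-firing V2as driven by a
#' bilateral tonic command are the rhythm engine; V0vs provide delayed
#' commissural excitation, dI6s commissural inhibition, and V1s ipsilateral
#' ascending inhibition. The dI6-to-contralateral-dI6 weights are scaled by
#' Gaussian(1, 0.1) draws, the symmetry-breaking noise required for left-right
#' alternation.
#'
#' @param variant \code{"base"} (bursting V0vs), \code{"bursting_v2a"}, or
#'   \code{"all_tonic"}.
#' @param n_somites 15 (base), 10, or 30.
#' @inheritParams build_single_coiling
#' @export
build_beat_and_glide <- function(variant = c("base", "bursting_v2a",
                                             "all_tonic"),
                                 n_somites = 15, overrides = NULL) {
  variant <- match.arg(variant)
  if (!n_somites %in% c(10, 15, 30))
    stop("beat-and-glide model supports 10, 15, or 30 somites")
  sheet_name <- switch(variant,
    base = "beat_glide_base",
    bursting_v2a = "beat_glide_bursting_v2a",
    all_tonic = "beat_glide_all_tonic")
  build_circuit(sheet_name, n_somites, overrides)
}

#' @export
print.spinal_circuit <- function(x, ...) {
  cat("Spinal circuit model:", x$name, "\n")
  cat("  somites:", x$n_somites, " neurons:", nrow(x$neurons),
      " connections:", nrow(x$connections), "\n")
  tab <- table(x$neurons$kind)
  cat("  populations:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  ck <- table(x$connections$kind)
  cat("  connection kinds:",
      paste(names(ck), as.integer(ck), sep = "=", collapse = ", "), "\n")
  cat("  E_gly:", x$constants$E_gly, "mV, cv:", x$constants$cv, "a.d.u./ms\n")
  invisible(x)
}

#' Export the connectome as an edge list
#'
#' @param circuit a \code{spinal_circuit}.
#' @param file optional path; when given, written as CSV.
#' @return data frame (pre, post, kind, weight, delay) with neuron labels.
#' @export
export_connectome <- function(circuit, file = NULL) {
  n <- circuit$neurons
  lab <- paste0(n$kind, "_", substr(n$side, 1, 1), n$index)
  out <- data.frame(
    pre = lab[circuit$connections$pre],
    post = lab[circuit$connections$post],
    kind = circuit$connections$kind,
    weight = circuit$connections$weight,
    delay = circuit$connections$delay,
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
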