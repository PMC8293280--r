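# Stylized SNc dopaminergic neuron morphologies: generation, SWC IO and
# d_lambda compartmentalization. A morphology is a tree of cylindrical
# sections; the soma is represented as a cylinder of length equal to its
# diameter (area pi * d^2, matching a sphere of the same diameter).

#' Passive membrane properties
#'
#' @param axial_resistivity Cytoplasmic resistivity (ohm cm).
#' @param specific_capacitance Membrane capacitance (uF/cm^2).
#' @param specific_membrane_resistance Membrane resistance (ohm cm^2); the
#'   leak conductance density is its reciprocal.
#' @param e_leak Leak reversal potential (mV).
#' @return Object of class `passive_spec`.
#' @export
passive_spec <- function(axial_resistivity = 150,
                         specific_capacitance = 0.75,
                         specific_membrane_resistance = 1e5,
                         e_leak = -50) {
  stopifnot(axial_resistivity > 0, specific_capacitance > 0,
            specific_membrane_resistance > 0)
  structure(list(axial_resistivity = axial_resistivity,
                 specific_capacitance = specific_capacitance,
                 specific_membrane_resistance = specific_membrane_resistance,
                 e_leak = e_leak),
            class = "passive_spec")
}

#' Spatial discretization policy (d_lambda rule)
#'
#' Sections are split into the smallest odd number of compartments such that
#' each compartment is no longer than `d_lambda` times the AC length constant
#' at `frequency`.
#'
#' @param d_lambda Fraction of the length constant (default 0.1).
#' @param frequency Reference frequency (Hz, default 100).
#' @export
discretization_policy <- function(d_lambda = 0.1, frequency = 100) {
  stopifnot(d_lambda > 0, d_lambda <= 1, frequency > 0)
  structure(list(d_lambda = d_lambda, frequency = frequency),
            class = "discretization_policy")
}

#' Morphology template for the stylized-population generator
#'
#' Ranges are sampled uniformly per cell; the defaults emulate large SNc
#' dopaminergic neurons (soma > 25 um) with 3-6 primary dendrites bearing
#' randomized branched subtrees and an axon-start / AIS / distal-axon chain.
#' Lengths and diameters in um.
#'
#' @param soma_diam Range of soma diameters.
#' @param n_dendrites Range (integer) of primary dendrite counts.
#' @param trunk_diam Range of primary dendrite diameters.
#' @param dend_length Range of dendritic section lengths.
#' @param taper Child/parent diameter ratio at branch points.
#' @param branch_prob Probability a dendritic section branches (per level).
#' @param max_depth Maximum branching depth below the trunk.
#' @param axon_start_length,ais_length,axon_length Axon chain lengths.
#' @param axon_start_diam,ais_diam,axon_diam Axon chain diameters.
#' @export
morph_template <- function(soma_diam = c(25, 30),
                           n_dendrites = c(3L, 6L),
                           trunk_diam = c(1.5, 3),
                           dend_length = c(80, 200),
                           taper = 0.7,
                           branch_prob = 0.7,
                           max_depth = 2L,
                           axon_start_length = 20,
                           ais_length = 30,
                           axon_length = 300,
                           axon_start_diam = 1.5,
                           ais_diam = 1.2,
                           axon_diam = 1) {
  as.list(environment())
}

new_morphology <- function(sections, id = "morph") {
  m <- structure(list(id = id, sections = sections), class = "kv_morphology")
  validate_morphology(m)
  m
}

#' @export
print.kv_morphology <- function(x, ...) {
  s <- x$sections
  cat("<kv_morphology>", x$id, ":", nrow(s), "sections,",
      sprintf("%.0f um^2 membrane\n", total_area(x)))
  print(table(s$kind))
  invisible(x)
}

validate_morphology <- function(m) {
  s <- m$sections
  need <- c("id", "kind", "parent", "length_um", "diam_um", "x", "y", "z")
  stopifnot(is.data.frame(s), all(need %in% names(s)))
  if (any(s$length_um <= 0) || any(s$diam_um <= 0)) {
    stop("section lengths and diameters must be positive")
  }
  if (sum(s$kind == "soma") != 1) stop("morphology must have exactly one soma")
  root <- s$id[s$parent == 0]
  if (length(root) != 1 || s$kind[s$id == root] != "soma") {
    stop("the unique root section must be the soma")
  }
  if (!all(s$parent[s$parent != 0] %in% s$id)) stop("dangling parent reference")
  # connected & acyclic: every section reaches the root through parents
  idx <- match(s$parent, s$id)
  for (i in seq_len(nrow(s))) {
    j <- i; steps <- 0
    while (s$parent[j] != 0) {
      j <- idx[j]; steps <- steps + 1
      if (steps > nrow(s)) stop("cycle detected in section tree")
    }
  }
  for (k in c("ais", "axon")) {
    at <- which(s$kind == k)
    if (length(at)) {
      pk <- s$kind[match(s$parent[at], s$id)]
      want <- if (k == "ais") "axon_start" else "ais"
      if (!all(pk == want)) stop(k, " must attach to ", want)
    }
  }
  invisible(m)
}

#' Total membrane area of a morphology (um^2)
#' @param m A `kv_morphology`.
#' @export
total_area <- function(m) {
  sum(pi * m$sections$diam_um * m$sections$length_um)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a population of stylized morphologies
#'
#' Pure function of `(n, seed, template)`: repeated calls with the same
#' arguments return identical populations.
#'
#' @param n Number of cells (`>= 1`).
#' @param seed Integer seed.
#' @param template A [morph_template()].
#' @return List of `kv_morphology`.
#' @export
generate_population <- function(n, seed = 1L, template = morph_template()) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, lapply(seq_len(n), function(i) {
    generate_one_morphology(template, id = sprintf("cell%02d", i))
  }))
}

rand_dir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

generate_one_morphology <- function(tpl, id) {
  rows <- list()
  add <- function(kind, parent, len, diam, origin) {
    id_new <- length(rows) + 1L
    p <- origin + len * rand_dir()
    rows[[id_new]] <<- data.frame(id = id_new, kind = kind, parent = parent,
                                  length_um = len, diam_um = diam,
                                  x = p[1], y = p[2], z = p[3])
    id_new
  }
  soma_d <- runif1(tpl$soma_diam)
  rows[[1]] <- data.frame(id = 1L, kind = "soma", parent = 0L,
                          length_um = soma_d, diam_um = soma_d,
                          x = 0, y = 0, z = 0)
  grow <- function(parent_id, diam, depth, origin) {
    sid <- add("dendrite", parent_id, runif1(tpl$dend_length), diam, origin)
    end <- unlist(rows[[sid]][c("x", "y", "z")])
    if (depth < tpl$max_depth && stats::runif(1) < tpl$branch_prob) {
      for (k in 1:2) grow(sid, diam * tpl$taper, depth + 1L, end)
    }
  }
  nd_vals <- seq(min(tpl$n_dendrites), max(tpl$n_dendrites))
  nd <- if (length(nd_vals) > 1) sample(nd_vals, 1) else nd_vals
  for (d in seq_len(nd)) grow(1L, runif1(tpl$trunk_diam), 0L, c(0, 0, 0))
  a1 <- add("axon_start", 1L, tpl$axon_start_length, tpl$axon_start_diam,
            c(0, 0, 0))
  a2 <- add("ais", a1, tpl$ais_length, tpl$ais_diam,
            unlist(rows[[a1]][c("x", "y", "z")]))
  add("axon", a2, tpl$axon_length, tpl$axon_diam,
      unlist(rows[[a2]][c("x", "y", "z")]))
  new_morphology(do.call(rbind, rows), id = id)
}

#' AC length constant
#'
#' `lambda_f = 1e5 * 0.5 * sqrt(d / (pi * f * Ra * Cm))` um, with `d` in um,
#' `Ra` in ohm cm and `Cm` in uF/cm^2; the 1e5 factor collects the unit
#' conversions.
#'
#' @param diameter Cable diameter (um), `> 0`.
#' @param passive A [passive_spec()].
#' @param frequency Reference frequency (Hz), `> 0`.
#' @return Length constant (um).
#' @export
lambda_f <- function(diameter, passive = passive_spec(), frequency = 100) {
  if (any(diameter <= 0) || frequency <= 0) stop("inputs must be positive")
  1e5 * 0.5 * sqrt(diameter / (pi * frequency * passive$axial_resistivity *
                                 passive$specific_capacitance))
}

# axial resistance of a half-compartment, in Mohm (d, l in um, Ra in ohm cm)
half_axial_mohm <- function(diam_um, len_um, ra) {
  ra * (len_um / 2 * 1e-4) / (pi * diam_um^2 / 4 * 1e-8) * 1e-6
}

#' Discretize a morphology into compartments
#'
#' Applies the d_lambda rule per section: the smallest odd number of
#' compartments whose length does not exceed `d_lambda * lambda_f(diam)`.
#' Compartment areas sum exactly to the section's cylinder area. Axial
#' coupling conductances (uS) connect adjacent compartment centers through
#' the two half-compartment resistances.
#'
#' @param m A `kv_morphology`.
#' @param policy A [discretization_policy()].
#' @param passive A [passive_spec()].
#' @return Data frame of compartments: `comp`, `section`, `kind`, `region`
#'   (somadendritic / ais / axon), `length_um`, `diam_um`, `area_um2`,
#'   `parent` (compartment index, 0 for the root) and `g_axial_uS` (coupling
#'   to the parent compartment).
#' @export
discretize <- function(m, policy = discretization_policy(),
                       passive = passive_spec()) {
  validate_morphology(m)
  s <- m$sections
  region_of <- c(soma = "somadendritic", dendrite = "somadendritic",
                 axon_start = "somadendritic", ais = "ais", axon = "axon")
  # topological order: parents before children (robust to arbitrary ids)
  topo <- integer(0)
  pending <- which(s$parent == 0)
  while (length(pending)) {
    i <- pending[1]; pending <- pending[-1]
    topo <- c(topo, i)
    pending <- c(pending, which(s$parent == s$id[i]))
  }
  out <- vector("list", nrow(s))
  last_comp <- stats::setNames(integer(nrow(s)), as.character(s$id))
  comp_n <- 0L
  for (i in topo) {
    lam <- lambda_f(s$diam_um[i], passive, policy$frequency)
    n <- ceiling(s$length_um[i] / (policy$d_lambda * lam))
    if (n %% 2 == 0) n <- n + 1L
    len <- s$length_um[i] / n
    parent_sec <- s$parent[i]
    comps <- data.frame(
      comp = comp_n + seq_len(n),
      section = s$id[i],
      kind = s$kind[i],
      region = unname(region_of[s$kind[i]]),
      length_um = len,
      diam_um = s$diam_um[i],
      area_um2 = pi * s$diam_um[i] * len,
      parent = c(if (parent_sec == 0) 0L
                 else last_comp[[as.character(parent_sec)]],
                 comp_n + seq_len(n - 1L))
    )
    comp_n <- comp_n + n
    last_comp[[as.character(s$id[i])]] <- comp_n
    out[[i]] <- comps
  }
  comps <- do.call(rbind, out[topo])
  rh <- half_axial_mohm(comps$diam_um, comps$length_um,
                        passive$axial_resistivity)
  g <- numeric(nrow(comps))
  has_parent <- comps$parent != 0
  g[has_parent] <- 1 / (rh[comps$parent[has_parent]] + rh[has_parent])
  comps$g_axial_uS <- g  # 1/Mohm = uS
  attr(comps, "morphology_id") <- m$id
  comps
}

#' Write a morphology to SWC
#'
#' One SWC node per section (plus the soma root node); the region
#' distinction among axon_start / AIS / axon, which standard SWC types
#' cannot carry, is written to a JSON sidecar `<path>.regions.json`.
#'
#' @param m A `kv_morphology`.
#' @param path Output file path.
#' @export
write_swc <- function(m, path) {
  validate_morphology(m)
  s <- m$sections
  type_of <- c(soma = 1L, axon_start = 2L, ais = 2L, axon = 2L, dendrite = 3L)
  df <- data.frame(n = s$id, type = unname(type_of[s$kind]),
                   x = s$x, y = s$y, z = s$z, r = s$diam_um / 2,
                   parent = ifelse(s$parent == 0, -1L, s$parent))
  lines <- c("# SWC export (one node per section; soma node is the root)",
             sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     df$n, df$type, df$x, df$y, df$z, df$r, df$parent))
  writeLines(lines, path)
  jsonlite::write_json(stats::setNames(as.list(s$kind), as.character(s$id)),
                       paste0(path, ".regions.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a morphology from SWC
#'
#' Standard 7-column SWC; each non-root node becomes one cylindrical section
#' whose length is the distance to its parent node. If the
#' `<path>.regions.json` sidecar written by [write_swc()] is present it
#' restores the axon_start / AIS / axon distinction; otherwise SWC types map
#' to soma (1), axon (2) and dendrite (3, 4).
#'
#' @param path SWC file path.
#' @param id Label for the morphology (default: file name).
#' @return A `kv_morphology`.
#' @export
read_swc <- function(path, id = basename(path)) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  line_no <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) {
    stop("malformed SWC at line ", line_no[bad[1]], ": expected 7 columns")
  }
  v <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7,
              byrow = TRUE)
  if (anyNA(v)) {
    stop("malformed SWC at line ",
         line_no[which(rowSums(is.na(v)) > 0)[1]], ": non-numeric field")
  }
  nodes <- data.frame(n = as.integer(v[, 1]), type = as.integer(v[, 2]),
                      x = v[, 3], y = v[, 4], z = v[, 5], r = v[, 6],
                      parent = as.integer(v[, 7]))
  orphan <- which(nodes$parent != -1 & !(nodes$parent %in% nodes$n))
  if (length(orphan)) {
    stop("orphan SWC node ", nodes$n[orphan[1]], " at line ",
         line_no[orphan[1]], ": parent ", nodes$parent[orphan[1]],
         " not present")
  }
  sidecar <- paste0(path, ".regions.json")
  kinds <- if (file.exists(sidecar)) {
    k <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    unname(unlist(k)[as.character(nodes$n)])
  } else {
    c("1" = "soma", "2" = "axon", "3" = "dendrite",
      "4" = "dendrite")[as.character(nodes$type)]
  }
  pidx <- match(nodes$parent, nodes$n)
  len <- ifelse(nodes$parent == -1, 2 * nodes$r,
                sqrt((nodes$x - nodes$x[pidx])^2 +
                     (nodes$y - nodes$y[pidx])^2 +
                     (nodes$z - nodes$z[pidx])^2))
  sec <- data.frame(id = nodes$n, kind = unname(kinds),
                    parent = ifelse(nodes$parent == -1, 0L, nodes$parent),
                    length_um = len, diam_um = 2 * nodes$r,
                    x = nodes$x, y = nodes$y, z = nodes$z)
  new_morphology(sec, id = id)
}
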