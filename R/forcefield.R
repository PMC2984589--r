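# AMBER-functional-form molecular mechanics:
#   E = sum k_r (r - r0)^2
#     + sum k_theta (theta - theta0)^2
#     + sum V_n/2 (1 + cos(n phi - gamma))
#     + sum eps [ (rmin/r)^12 - 2 (rmin/r)^6 ]      (1-4 / scnb)
#     + sum 332.0637 q_i q_j / r                    (1-4 / scee)
# with 1-2 and 1-3 pairs excluded and hard cutoff truncation.

ff_cache <- new.env(parent = emptyenv())

#' Load force-field parameters
#'
#' Text file with sections `[options]` (scee, scnb, coulomb, cutoff),
#' `[types]` (`name rmin2 eps mass`), `[stretch]` (`t1 t2 k r0`),
#' `[bend]` (`t1 t2 t3 k theta0`) and `[torsion]`
#' (`t1 t2 t3 t4 vn2 n gamma`, `X` = wildcard, multiple terms per
#' quadruple allowed). Wildcard torsions match only when no exact
#' entry exists.
#'
#' @param path parameter file; default: the bundled minimal
#'   amino-acid + water set.
#' @return a `ff_params` list.
#' @export
load_ff_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ff_params.txt", package = "molkit",
                        mustWork = TRUE)
  if (!is.null(ff_cache[[path]])) return(ff_cache[[path]])
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  section <- ""
  types <- list(); stretch <- list(); bend <- list(); torsion <- list()
  opts <- list(scee = 1.2, scnb = 2.0, coulomb = COULOMB_CONSTANT,
               cutoff = 12.0)
  for (line in lines) {
    if (startsWith(line, "[")) { section <- gsub("[][]", "", line); next }
    f <- strsplit(line, "[[:space:]]+")[[1]]
    if (section == "options") {
      opts[[f[1]]] <- as.numeric(f[2])
    } else if (section == "types") {
      types[[f[1]]] <- list(rmin2 = as.numeric(f[2]), eps = as.numeric(f[3]),
                            mass = as.numeric(f[4]))
    } else if (section == "stretch") {
      key <- paste(sort(f[1:2]), collapse = " ")
      stretch[[key]] <- c(k = as.numeric(f[3]), r0 = as.numeric(f[4]))
    } else if (section == "bend") {
      t <- f[1:3]
      if (t[1] > t[3]) t <- rev(t)
      bend[[paste(t, collapse = " ")]] <-
        c(k = as.numeric(f[4]), theta0 = as.numeric(f[5]))
    } else if (section == "torsion") {
      t <- f[1:4]
      if (t[2] > t[3] || (t[2] == t[3] && t[1] > t[4])) t <- rev(t)
      key <- paste(t, collapse = " ")
      torsion[[key]] <- rbind(torsion[[key]],
                              c(vn2 = as.numeric(f[5]), n = as.numeric(f[6]),
                                gamma = as.numeric(f[7])))
    }
  }
  p <- structure(list(types = types, stretch = stretch, bend = bend,
                      torsion = torsion, opts = opts), class = "ff_params")
  ff_cache[[path]] <- p
  p
}

#' Assign force-field types and partial charges from templates
#'
#' Every atom receives the type and charge of its fragment-template
#' atom (matched by residue name, terminal variant and atom name).
#'
#' @param sys a `molsys` with normalized names.
#' @param db a `fragment_db`.
#' @return invisibly, the system.
#' @export
assign_types_and_charges <- function(sys, db = load_fragment_db()) {
  flag_termini(sys)
  offenders <- character()
  for (ri in seq_len(nrow(sys$residues))) {
    tpl <- frag_template(db, sys$residues$name[ri], residue_variant(sys, ri))
    for (ai in which(sys$atoms$res == ri)) {
      k <- if (is.null(tpl)) NA_integer_ else
        match(sys$atoms$name[ai], tpl$atoms$name)
      if (is.na(k)) {
        offenders <- c(offenders, sprintf("%s %d / %s",
                                          sys$residues$name[ri],
                                          sys$residues$id[ri],
                                          sys$atoms$name[ai]))
      } else {
        sys$atoms$type[ai] <- tpl$atoms$type[k]
        sys$atoms$charge[ai] <- tpl$atoms$charge[k]
      }
    }
  }
  if (length(offenders))
    stop("force-field setup failed; untyped atoms:\n  ",
         paste(offenders, collapse = "\n  "))
  invisible(sys)
}

lookup_stretch <- function(params, t1, t2) {
  params$stretch[[paste(sort(c(t1, t2)), collapse = " ")]]
}

lookup_bend <- function(params, t1, t2, t3) {
  t <- c(t1, t2, t3)
  if (t[1] > t[3]) t <- rev(t)
  params$bend[[paste(t, collapse = " ")]]
}

lookup_torsion <- function(params, t1, t2, t3, t4) {
  t <- c(t1, t2, t3, t4)
  if (t[2] > t[3] || (t[2] == t[3] && t[1] > t[4])) t <- rev(t)
  exact <- params$torsion[[paste(t, collapse = " ")]]
  if (!is.null(exact)) return(exact)
  for (key in list(c("X", t[2], t[3], t[4]), c(t[1], t[2], t[3], "X"),
                   c("X", t[2], t[3], "X"))) {
    k <- key
    if (k[2] > k[3] || (k[2] == k[3] && k[1] > k[4])) k <- rev(k)
    hit <- params$torsion[[paste(k, collapse = " ")]]
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Build interaction lists for a system
#'
#' Stretches = bonds; bends = all connected triples; torsions = all
#' connected quadruples (each once, multi-term); nonbonded pairs
#' partitioned into excluded (1-2, 1-3), scaled 1-4, and full.
#'
#' @param sys a typed, bonded `molsys`.
#' @param params a `ff_params`.
#' @return an `interaction_lists` list.
#' @export
build_interactions <- function(sys, params = load_ff_params()) {
  n <- n_atoms(sys)
  ty <- sys$atoms$type
  if (anyNA(ty)) stop("atoms without force-field types; run assign_types_and_charges()")
  b <- sys$bonds
  missing <- character()

  ## adjacency
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  adj <- lapply(adj, sort)

  ## stretches
  st <- NULL
  if (nrow(b)) {
    kk <- r0 <- numeric(nrow(b))
    for (k in seq_len(nrow(b))) {
      p <- lookup_stretch(params, ty[b$i[k]], ty[b$j[k]])
      if (is.null(p)) {
        missing <- c(missing, paste("stretch", ty[b$i[k]], ty[b$j[k]]))
        next
      }
      kk[k] <- p["k"]; r0[k] <- p["r0"]
    }
    st <- data.frame(i = b$i, j = b$j, k = kk, r0 = r0)
  } else st <- data.frame(i = integer(), j = integer(), k = numeric(),
                          r0 = numeric())

  ## bends
  bi <- bj <- bk <- integer(); bkk <- bt0 <- numeric()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (c in seq_len(a - 1)) {
      i <- nb[c]; k <- nb[a]
      p <- lookup_bend(params, ty[i], ty[j], ty[k])
      if (is.null(p)) {
        missing <- c(missing, paste("bend", ty[i], ty[j], ty[k]))
        next
      }
      bi <- c(bi, i); bj <- c(bj, j); bk <- c(bk, k)
      bkk <- c(bkk, p["k"]); bt0 <- c(bt0, p["theta0"])
    }
  }
  bends <- data.frame(i = bi, j = bj, k = bk, kth = bkk, theta0 = bt0)

  ## torsions: one row per (quadruple, term)
  ti <- tj <- tk <- tl <- integer(); tv <- tn <- tg <- numeric()
  for (bb in seq_len(nrow(b))) {
    j <- b$i[bb]; k <- b$j[bb]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next  # three-membered ring
      terms <- lookup_torsion(params, ty[i], ty[j], ty[k], ty[l])
      if (is.null(terms)) {
        missing <- c(missing,
                     paste("torsion", ty[i], ty[j], ty[k], ty[l]))
        next
      }
      for (tt in seq_len(nrow(terms))) {
        ti <- c(ti, i); tj <- c(tj, j); tk <- c(tk, k); tl <- c(tl, l)
        tv <- c(tv, terms[tt, "vn2"]); tn <- c(tn, terms[tt, "n"])
        tg <- c(tg, terms[tt, "gamma"])
      }
    }
  }
  tors <- data.frame(i = ti, j = tj, k = tk, l = tl,
                     vn2 = tv, n = tn, gamma = tg)
  if (length(missing))
    stop("missing force-field parameters for:\n  ",
         paste(unique(missing), collapse = "\n  "))

  ## exclusion classes from graph distances 1..3
  pair_key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  excl <- unique(c(
    if (nrow(b)) pair_key(b$i, b$j),
    if (nrow(bends)) pair_key(bends$i, bends$k)))
  sc14 <- if (nrow(tors)) unique(pair_key(tors$i, tors$l)) else integer()
  sc14 <- setdiff(sc14, excl)

  pairs_i <- integer(); pairs_j <- integer()
  if (n > 1) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs_i <- idx[, 1]; pairs_j <- idx[, 2]
  }
  keys <- pair_key(pairs_i, pairs_j)
  cls <- rep("full", length(keys))
  cls[keys %in% sc14] <- "scaled_1_4"
  cls[keys %in% excl] <- "excluded"
  keep <- cls != "excluded"
  q <- sys$atoms$charge
  rmin2 <- vapply(ty, function(t) {
    tp <- params$types[[t]]
    if (is.null(tp)) stop("no vdW parameters for type ", t)
    tp$rmin2
  }, numeric(1))
  eps <- vapply(ty, function(t) params$types[[t]]$eps, numeric(1))
  nb <- data.frame(i = pairs_i[keep], j = pairs_j[keep],
                   scaled = cls[keep] == "scaled_1_4")
  nb$rmin <- rmin2[nb$i] + rmin2[nb$j]
  nb$eps <- sqrt(eps[nb$i] * eps[nb$j])
  nb$qq <- q[nb$i] * q[nb$j]

  structure(list(stretches = st, bends = bends, torsions = tors,
                 nonbonded = nb, masses = vapply(ty, function(t)
                   params$types[[t]]$mass, numeric(1)),
                 opts = params$opts, natoms = n),
            class = "interaction_lists")
}

#' Set up a force field on a system
#'
#' Assigns types and charges (unless already present), builds
#' interaction lists and captures the movable-atom mask from the
#' current selection (no selection = all atoms movable). The full
#' system always contributes to the energy; only movable atoms are
#' displaced by minimizers and dynamics.
#'
#' @param sys a prepared `molsys` (names normalized, bonds built).
#' @param db a `fragment_db`.
#' @param params a `ff_params`.
#' @param cutoff nonbonded cutoff override, Angstrom (0 = none).
#' @return a `forcefield` object.
#' @export
ff_setup <- function(sys, db = load_fragment_db(),
                     params = load_ff_params(), cutoff = NULL) {
  if (anyNA(sys$atoms$type)) assign_types_and_charges(sys, db)
  lists <- build_interactions(sys, params)
  if (!is.null(cutoff)) lists$opts$cutoff <- cutoff
  ff <- list(sys = sys, lists = lists,
             movable = set_movable_from_selection(sys))
  class(ff) <- "forcefield"
  ff
}

#' Movable-atom mask from selection flags
#'
#' An empty selection makes every atom movable; otherwise exactly the
#' selected atoms move.
#'
#' @param sys a `molsys`.
#' @return logical mask over atoms.
#' @export
set_movable_from_selection <- function(sys) {
  sel <- sys$atoms$selected
  if (!any(sel)) rep(TRUE, length(sel)) else sel
}

#' Compute the potential energy of a configuration
#'
#' @param ff a `forcefield` from [ff_setup()], or `interaction_lists`.
#' @param xyz optional coordinate matrix (default: the system's
#'   current coordinates).
#' @return an `energy_report` list: total, stretch, bend, torsion,
#'   vdw, electrostatic (kcal/mol).
#' @export
compute_energy <- function(ff, xyz = NULL) {
  eg <- ff_eval(ff, xyz, gradient = FALSE)
  eg$report
}

#' Compute the analytic energy gradient
#'
#' @param ff a `forcefield`.
#' @param xyz optional coordinate matrix.
#' @return n x 3 matrix of dE/dx (kcal/mol/Angstrom); the full system
#'   gradient, unmasked.
#' @export
compute_gradient <- function(ff, xyz = NULL) {
  ff_eval(ff, xyz, gradient = TRUE)$gradient
}

## Shared energy/gradient kernel, vectorized over interaction lists.
ff_eval <- function(ff, xyz = NULL, gradient = TRUE) {
  lists <- if (inherits(ff, "forcefield")) ff$lists else ff
  if (is.null(xyz)) {
    if (!inherits(ff, "forcefield")) stop("xyz required")
    xyz <- coords(ff$sys)
  }
  n <- lists$natoms
  g <- if (gradient) matrix(0, n, 3) else NULL
  acc <- function(idx, contrib) {
    ## accumulate 3-vector contributions per atom index
    for (d in 1:3)
      g[, d] <<- g[, d] + tabulate_num(idx, contrib[, d], n)
  }

  e_stretch <- e_bend <- e_tors <- e_vdw <- e_elec <- 0

  st <- lists$stretches
  if (nrow(st)) {
    dvec <- xyz[st$i, , drop = FALSE] - xyz[st$j, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    e_stretch <- sum(st$k * (r - st$r0)^2)
    if (gradient) {
      coef <- 2 * st$k * (r - st$r0) / r
      gi <- dvec * coef
      acc(st$i, gi); acc(st$j, -gi)
    }
  }

  bd <- lists$bends
  if (nrow(bd)) {
    u <- xyz[bd$i, , drop = FALSE] - xyz[bd$j, , drop = FALSE]
    v <- xyz[bd$k, , drop = FALSE] - xyz[bd$j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cth <- rowSums(u * v) / (nu * nv)
    cth <- pmax(-1, pmin(1, cth))
    th <- acos(cth)
    th0 <- bd$theta0 * DEG
    kth <- bd$kth  # kcal/mol/rad^2
    e_bend <- sum(kth * (th - th0)^2)
    if (gradient) {
      sth <- sqrt(pmax(1e-12, 1 - cth^2))
      dEdth <- 2 * kth * (th - th0)
      uh <- u / nu; vh <- v / nv
      dthdi <- (uh * cth - vh) / (nu * sth)
      dthdk <- (vh * cth - uh) / (nv * sth)
      gi <- dthdi * dEdth
      gk <- dthdk * dEdth
      acc(bd$i, gi); acc(bd$k, gk); acc(bd$j, -(gi + gk))
    }
  }

  to <- lists$torsions
  if (nrow(to)) {
    b1 <- xyz[to$j, , drop = FALSE] - xyz[to$i, , drop = FALSE]
    b2 <- xyz[to$k, , drop = FALSE] - xyz[to$j, , drop = FALSE]
    b3 <- xyz[to$l, , drop = FALSE] - xyz[to$k, , drop = FALSE]
    n1 <- rowcross(b1, b2)
    n2 <- rowcross(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    m1 <- rowcross(n1, b2 / nb2)
    phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
    gam <- to$gamma * DEG
    e_tors <- sum(to$vn2 * (1 + cos(to$n * phi - gam)))
    if (gradient) {
      dEdphi <- -to$vn2 * to$n * sin(to$n * phi - gam)
      n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
      dphidi <- n1 * (nb2 / n1sq)
      dphidl <- -n2 * (nb2 / n2sq)
      f1 <- rowSums(b1 * b2) / nb2^2
      f2 <- rowSums(b3 * b2) / nb2^2
      dphidj <- -dphidi * (1 + f1) + dphidl * f2
      dphidk <- -(dphidi + dphidj + dphidl)
      acc(to$i, dphidi * dEdphi)
      acc(to$j, dphidj * dEdphi)
      acc(to$k, dphidk * dEdphi)
      acc(to$l, dphidl * dEdphi)
    }
  }

  nb <- lists$nonbonded
  if (nrow(nb)) {
    dvec <- xyz[nb$i, , drop = FALSE] - xyz[nb$j, , drop = FALSE]
    r2 <- rowSums(dvec^2)
    if (any(r2 < 1e-12)) stop("singular nonbonded distance")
    cutoff <- lists$opts$cutoff
    live <- if (cutoff > 0) r2 <= cutoff^2 else rep(TRUE, length(r2))
    r <- sqrt(r2)
    scee <- ifelse(nb$scaled, lists$opts$scee, 1)
    scnb <- ifelse(nb$scaled, lists$opts$scnb, 1)
    sr6 <- (nb$rmin / r)^6
    evdw_pair <- nb$eps * (sr6^2 - 2 * sr6) / scnb
    eel_pair <- lists$opts$coulomb * nb$qq / (r * scee)
    e_vdw <- sum(evdw_pair[live])
    e_elec <- sum(eel_pair[live])
    if (gradient) {
      dvdw <- 12 * nb$eps * (sr6 - sr6^2) / (scnb * r)
      delec <- -eel_pair / r
      coef <- ifelse(live, (dvdw + delec) / r, 0)
      gi <- dvec * coef
      acc(nb$i, gi); acc(nb$j, -gi)
    }
  }

  report <- list(stretch = e_stretch, bend = e_bend, torsion = e_tors,
                 vdw = e_vdw, electrostatic = e_elec)
  report$total <- e_stretch + e_bend + e_tors + e_vdw + e_elec
  class(report) <- "energy_report"
  list(report = report, gradient = g)
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("E_total = %.6f kcal/mol  (stretch %.4f, bend %.4f, ",
                     "torsion %.4f, vdw %.4f, elec %.4f)\n"),
              x$total, x$stretch, x$bend, x$torsion, x$vdw,
              x$electrostatic))
  invisible(x)
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Sum `values` into bins given by `idx` (like tabulate, but numeric).
tabulate_num <- function(idx, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
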