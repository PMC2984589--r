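# Bond-order perception: penalty-scored enumeration of bond-order
# assignments (branch and bound), kekulization (perfect matching on
# the aromatic subgraph), aromaticity perception (SSSR + Hueckel
# counting).

#' Load the atomic valence-penalty table
#'
#' Rows `element charge valence penalty` list the zero-penalty (or
#' explicitly penalized) valence sums per element/charge. Valence sums
#' not listed cost `32 * |distance to the nearest listed valence|`.
#'
#' @param path table file; default: the bundled table (C 4; N 3 / N+ 4;
#'   O 2 / O- 1; S 2,4,6; P 3,5; H 1; halogens 1).
#' @return an `atom_penalty_table` data frame.
#' @export
load_penalty_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bond_order_penalties.txt",
                        package = "molkit", mustWork = TRUE)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  tab <- do.call(rbind, lapply(lines, function(l) {
    f <- strsplit(l, "[[:space:]]+")[[1]]
    data.frame(element = f[1], charge = as.integer(f[2]),
               valence = as.integer(f[3]), penalty = as.integer(f[4]),
               stringsAsFactors = FALSE)
  }))
  class(tab) <- c("atom_penalty_table", class(tab))
  tab
}

## Penalty of one atom at a given valence sum.
atom_penalty <- function(table, element, charge, valence_sum) {
  rows <- table[table$element == element & table$charge == charge, ,
                drop = FALSE]
  if (!nrow(rows))
    rows <- table[table$element == element & table$charge == 0L, ,
                  drop = FALSE]
  if (!nrow(rows)) stop("unsupported element in penalty table: ", element)
  exact <- rows$penalty[rows$valence == valence_sum]
  if (length(exact)) return(min(exact))
  32L * min(abs(rows$valence - valence_sum))
}

#' Enumerate bond-order assignments sorted by penalty
#'
#' Branch-and-bound search over order assignments {1,2,3} for every
#' bond between heavy atoms (bonds to hydrogen stay single). The
#' penalty of an assignment is the sum over atoms of the valence
#' penalty of (bond-order sum + attached hydrogens). Results are
#' sorted ascending by total penalty, ties broken lexicographically by
#' bond order vector; the first result is globally minimal.
#'
#' @param sys a `molsys` with connectivity (orders may be arbitrary).
#' @param table an `atom_penalty_table`.
#' @param max_results maximum number of assignments returned.
#' @param max_penalty prune assignments with penalty above this.
#' @return list of `list(orders, penalty)`, orders indexed like
#'   `sys$bonds`.
#' @export
assign_bond_orders <- function(sys, table = load_penalty_table(),
                               max_results = 10, max_penalty = 128L) {
  b <- sys$bonds
  el <- sys$atoms$element
  fc <- sys$atoms$formal_charge
  free <- which(el[b$i] != "H" & el[b$j] != "H")
  fixed_orders <- rep(1, nrow(b))  # X-H bonds stay single

  ## per-atom fixed valence contribution (H neighbours etc.)
  n <- n_atoms(sys)
  hcount <- numeric(n)
  for (k in seq_len(nrow(b))) {
    if (k %in% free) next
    hcount[b$i[k]] <- hcount[b$i[k]] + 1
    hcount[b$j[k]] <- hcount[b$j[k]] + 1
  }
  heavy <- which(el != "H")
  for (a in heavy) if (!length(atom_bonds(sys, a)) && !(a %in% b$i) &&
                       !(a %in% b$j)) hcount[a] <- hcount[a]

  ## atoms influenced by each free bond; bond order: as given (document)
  results <- list()
  nfree <- length(free)
  if (!nfree) {
    pen <- sum(vapply(heavy, function(a)
      atom_penalty(table, el[a], fc[a],
                   sum(fixed_orders[atom_bonds(sys, a)])), numeric(1)))
    return(list(list(orders = fixed_orders, penalty = pen)))
  }

  ## precompute, per free-bond position, the atoms whose bonds are all
  ## decided once bonds 1..k are set
  bonds_of_atom <- lapply(seq_len(n), function(a) atom_bonds(sys, a))
  last_bond_pos <- vapply(heavy, function(a) {
    fb <- intersect(bonds_of_atom[[a]], free)
    if (!length(fb)) 0L else max(match(fb, free))
  }, integer(1))

  orders <- fixed_orders
  recurse <- function(pos, partial_penalty) {
    if (partial_penalty > max_penalty) return()
    if (length(results) >= 4 * max_results &&
        partial_penalty > results[[length(results)]]$penalty) {
      ## cheap bound: worse than the current worst kept result
    }
    if (pos > nfree) {
      results[[length(results) + 1L]] <<-
        list(orders = orders, penalty = partial_penalty)
      return()
    }
    for (o in c(1, 2, 3)) {
      orders[free[pos]] <<- o
      ## add penalties of atoms fully decided at this position
      done <- heavy[last_bond_pos == pos]
      add <- 0
      ok <- TRUE
      for (a in done) {
        vs <- sum(orders[bonds_of_atom[[a]]])
        p <- atom_penalty(table, el[a], fc[a], vs)
        add <- add + p
      }
      if (ok) recurse(pos + 1, partial_penalty + add)
    }
    orders[free[pos]] <<- 1
  }
  base_penalty <- sum(vapply(heavy[last_bond_pos == 0L], function(a)
    atom_penalty(table, el[a], fc[a], sum(fixed_orders[bonds_of_atom[[a]]])),
    numeric(1)))
  recurse(1, base_penalty)

  if (!length(results)) return(list())
  ord_key <- vapply(results, function(r)
    paste(sprintf("%d", r$orders[free]), collapse = ""), character(1))
  pens <- vapply(results, `[[`, numeric(1), "penalty")
  o <- order(pens, ord_key)
  results <- results[o]
  results[seq_len(min(max_results, length(results)))]
}

#' Apply a bond-order assignment to a system
#' @param sys a `molsys`.
#' @param assignment one element of the [assign_bond_orders()] result.
#' @return invisibly, the system.
#' @export
apply_bond_orders <- function(sys, assignment) {
  sys$bonds$order <- assignment$orders
  invisible(sys)
}

## -------------------------------------------------------------------
## Ring perception: smallest set of smallest rings via per-edge
## shortest cycles reduced over the cycle space.

#' Smallest set of smallest rings
#'
#' For every bond, finds the shortest cycle through it (breadth-first
#' search with the bond removed), then reduces the candidate rings to
#' a linearly independent basis of size |E| - |V| + components,
#' preferring smaller rings (deterministic order).
#'
#' @param sys a `molsys`.
#' @return list of integer atom-index vectors, one per ring.
#' @export
find_sssr <- function(sys) {
  n <- n_atoms(sys)
  b <- sys$bonds
  if (!nrow(b)) return(list())
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  shortest_path <- function(from, to, banned_edge) {
    prev <- rep(NA_integer_, n)
    seen <- rep(FALSE, n)
    seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nxt in adj[[cur]]) {
        if ((cur == banned_edge[1] && nxt == banned_edge[2]) ||
            (cur == banned_edge[2] && nxt == banned_edge[1])) next
        if (!seen[nxt]) {
          seen[nxt] <- TRUE
          prev[nxt] <- cur
          if (nxt == to) {
            path <- nxt
            while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
            return(path)
          }
          queue <- c(queue, nxt)
        }
      }
    }
    NULL
  }
  candidates <- list()
  for (k in seq_len(nrow(b))) {
    p <- shortest_path(b$i[k], b$j[k], c(b$i[k], b$j[k]))
    if (!is.null(p)) candidates[[length(candidates) + 1L]] <- p
  }
  if (!length(candidates)) return(list())
  ## deduplicate and sort by size then lexicographic
  keyof <- function(ring) paste(sort(ring), collapse = ",")
  keys <- vapply(candidates, keyof, character(1))
  candidates <- candidates[!duplicated(keys)]
  sizes <- lengths(candidates)
  candidates <- candidates[order(sizes, vapply(candidates, keyof,
                                               character(1)))]
  ## cycle-space target dimension
  comp <- graph_components(adj, n)
  target <- nrow(b) - n + comp
  ## greedy GF(2) independence over edge-incidence vectors
  edge_index <- function(i, j) {
    which((b$i == min(i, j)) & (b$j == max(i, j)))
  }
  basis <- list()
  chosen <- list()
  for (ring in candidates) {
    if (length(chosen) >= target) break
    vec <- rep(0L, nrow(b))
    m <- length(ring)
    for (t in seq_len(m)) {
      e <- edge_index(ring[t], ring[t %% m + 1])
      vec[e] <- 1L
    }
    red <- vec
    for (bv in basis) {
      piv <- which(bv == 1L)[1]
      if (red[piv] == 1L) red <- xor(red, bv) * 1L
    }
    if (any(red == 1L)) {
      basis[[length(basis) + 1L]] <- red
      chosen[[length(chosen) + 1L]] <- ring
    }
  }
  chosen
}

graph_components <- function(adj, n) {
  seen <- rep(FALSE, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nxt in adj[[cur]]) if (!seen[nxt]) {
        seen[nxt] <- TRUE; queue <- c(queue, nxt)
      }
    }
  }
  comp
}

## -------------------------------------------------------------------
## Kekulization

## Is an aromatic atom a pi-electron-pair donor (pyrrole-type): gets no
## double bond in any Kekule structure?
pyrrole_type <- function(sys, a, arom_deg, explicit_h) {
  el <- sys$atoms$element[a]
  fc <- sys$atoms$formal_charge[a]
  nb <- atom_neighbors(sys, a)
  nH <- sum(sys$atoms$element[nb] == "H")
  if (!is.na(explicit_h[a]) && explicit_h[a] > 0) nH <- nH + explicit_h[a]
  subst <- length(nb) + (if (!is.na(explicit_h[a]) && explicit_h[a] > 0)
    explicit_h[a] else 0)
  if (el == "C") return(FALSE)
  if (el %in% c("O", "S")) return(TRUE)        # furan/thiophene type
  if (el == "N") {
    if (fc > 0) return(FALSE)                  # pyridinium-type keeps a double
    ## N with three sigma partners (incl. H) has no free valence slot
    return(subst >= 3)
  }
  FALSE
}

#' Kekulize aromatic bonds
#'
#' Replaces every aromatic bond by alternating single/double orders by
#' computing a perfect matching on the subgraph of aromatic atoms that
#' must carry exactly one double bond (pyrrole-type N/O/S contribute a
#' lone pair and are excluded from the matching).
#'
#' @param sys a `molsys` whose aromatic bonds form rings.
#' @return invisibly, the system.
#' @export
kekulize <- function(sys) {
  arom <- which(sys$bonds$order == BOND_AROMATIC)
  if (!length(arom)) return(invisible(sys))
  explicit_h <- attr(sys, "explicit_h") %||% rep(NA_integer_, n_atoms(sys))
  atoms <- sort(unique(c(sys$bonds$i[arom], sys$bonds$j[arom])))
  arom_deg <- table(c(sys$bonds$i[arom], sys$bonds$j[arom]))
  needs_double <- atoms[!vapply(atoms, function(a)
    pyrrole_type(sys, a, arom_deg, explicit_h), logical(1))]

  ## backtracking perfect matching on `needs_double` over aromatic edges
  edges <- lapply(arom, function(k) c(sys$bonds$i[k], sys$bonds$j[k]))
  matched <- rep(FALSE, n_atoms(sys))
  chosen <- logical(length(arom))
  order_free <- order(vapply(seq_along(arom), function(t) min(edges[[t]]),
                             numeric(1)))
  solve <- function(todo) {
    if (!length(todo)) return(TRUE)
    a <- todo[1]
    if (matched[a]) return(solve(todo[-1]))
    for (t in seq_along(arom)) {
      e <- edges[[t]]
      if (!(a %in% e)) next
      other <- setdiff(e, a)
      if (matched[other] || !(other %in% needs_double)) next
      matched[a] <<- TRUE; matched[other] <<- TRUE; chosen[t] <<- TRUE
      if (solve(todo[-1])) return(TRUE)
      matched[a] <<- FALSE; matched[other] <<- FALSE; chosen[t] <<- FALSE
    }
    FALSE
  }
  if (!solve(needs_double))
    stop("non-kekulizable aromatic system")
  sys$bonds$order[arom] <- ifelse(chosen, 2, 1)
  invisible(sys)
}

#' Perceive aromatic rings (Hueckel rule)
#'
#' Computes the SSSR and marks every bond of a qualifying ring
#' aromatic. A ring qualifies when all members are sp2-capable C/N/O/S
#' (no sp3 centres: every ring carbon carries a double bond or a
#' positive charge allowance) and the ring pi-electron count satisfies
#' 4n+2 (double-bond atom: 1; pyrrole-type heteroatom: 2;
#' carbocation: 0).
#'
#' @param sys a `molsys` with definite bond orders.
#' @return invisibly, the system (qualifying bonds set to
#'   [BOND_AROMATIC]).
#' @export
perceive_aromaticity <- function(sys) {
  rings <- find_sssr(sys)
  if (!length(rings)) return(invisible(sys))
  el <- sys$atoms$element
  fc <- sys$atoms$formal_charge
  bond_row <- function(i, j) which(sys$bonds$i == min(i, j) &
                                   sys$bonds$j == max(i, j))
  has_double <- function(a) {
    any(sys$bonds$order[atom_bonds(sys, a)] %in% c(2, BOND_AROMATIC))
  }
  mark <- integer()
  for (ring in rings) {
    ok <- TRUE
    pi_e <- 0
    for (a in ring) {
      if (!el[a] %in% c("C", "N", "O", "S")) { ok <- FALSE; break }
      if (has_double(a)) {
        ## in-ring double? an exocyclic double (e.g. quinone C=O) makes
        ## the atom sp2 but contributes no ring pi electron; require the
        ## double bond to lie in the ring for the +1 count
        ring_dbl <- FALSE
        for (nb in atom_neighbors(sys, a)) {
          if (nb %in% ring &&
              sys$bonds$order[bond_row(a, nb)] %in% c(2, BOND_AROMATIC)) {
            ring_dbl <- TRUE
            break
          }
        }
        if (ring_dbl) pi_e <- pi_e + 1
        else { ok <- FALSE; break }  # cross-conjugated: not aromatic here
      } else if (el[a] %in% c("N", "O", "S") && fc[a] <= 0) {
        pi_e <- pi_e + 2            # lone-pair donor
      } else if (el[a] == "C" && fc[a] == 1) {
        pi_e <- pi_e + 0            # carbocation
      } else {
        ok <- FALSE; break          # sp3 centre
      }
    }
    if (ok && pi_e %% 4 == 2) {
      m <- length(ring)
      for (t in seq_len(m))
        mark <- c(mark, bond_row(ring[t], ring[t %% m + 1]))
    }
  }
  if (length(mark)) sys$bonds$order[unique(mark)] <- BOND_AROMATIC
  invisible(sys)
}
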