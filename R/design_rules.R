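# Azeotropy design rules: checks on the interaction matrix that force all
# unbonded-patch probabilities equal, and the reduced scalar mass-balance
# equation they imply.

# Table of all patches in the mixture with per-species partner counts.
# Partners are counted through colors with multiplicity: a patch of color c
# has, on species j, one partner per patch slot of j whose color d satisfies
# entries[c, d] == 1.
patch_partner_table <- function(mixture) {
  ents <- mixture$matrix$entries
  rows <- list()
  for (i in seq_len(mixture$n_species)) {
    cols_i <- mixture$species[[i]]$patch_colors
    for (a in seq_along(cols_i)) {
      cnt <- vapply(seq_len(mixture$n_species), function(j) {
        sum(ents[cols_i[a], mixture$species[[j]]$patch_colors])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        species = i, slot = a, color = cols_i[a],
        t(setNames(cnt, paste0("partners_sp", seq_along(cnt)))),
        partners_total = sum(cnt))
    }
  }
  do.call(rbind, rows)
}

rule_report <- function(rule, satisfied, predicted_azeotrope = NULL,
                        multiplicity_n = NULL, m = NULL, n_species = NULL,
                        details = NULL) {
  structure(list(rule = rule, satisfied = satisfied,
                 predicted_azeotrope = predicted_azeotrope,
                 multiplicity_n = multiplicity_n, m = m,
                 n_species = n_species, details = details),
            class = "rule_report")
}

#' @export
print.rule_report <- function(x, ...) {
  cat(sprintf("design rule '%s': %s\n", x$rule,
              if (x$satisfied) "satisfied" else "NOT satisfied"))
  if (x$satisfied) {
    if (identical(x$predicted_azeotrope, "all"))
      cat("predicted azeotrope: every composition (always azeotropic)\n")
    else
      cat("predicted azeotrope: x = (",
          paste(signif(x$predicted_azeotrope, 6), collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Check the bond exclusivity condition
#'
#' Satisfied when every patch in the system (over all species, counting color
#' placements with multiplicity) has exactly one bonding partner.  The design
#' then carries an azeotrope at the equimolar composition `1/N_s`.
#'
#' @param mixture a [mixture_spec()].
#' @return a `rule_report`.
#' @export
check_bond_exclusivity <- function(mixture) {
  tab <- patch_partner_table(mixture)
  ok <- all(tab$partners_total == 1)
  rule_report("exclusivity", ok,
              predicted_azeotrope = if (ok)
                rep(1 / mixture$n_species, mixture$n_species),
              m = 1L, n_species = mixture$n_species, details = tab)
}

#' Check the bond multiplicity condition (binary mixtures)
#'
#' Satisfied when every patch either has exactly one partner located on
#' species 2 (and none elsewhere) or exactly `n` partners on species 1 (and
#' none elsewhere).  The design then carries an azeotrope at
#' `x = (1/(n+1), n/(n+1))`.  With `n = 1` this reduces to bond exclusivity.
#'
#' @param mixture a binary [mixture_spec()].
#' @param n bond multiplicity toward species 1 (`n >= 1`).
#' @return a `rule_report`.
#' @export
check_bond_multiplicity <- function(mixture, n) {
  if (mixture$n_species != 2)
    stop("bond multiplicity rule supports binary mixtures only")
  stopifnot(n >= 1)
  tab <- patch_partner_table(mixture)
  ok_patch <- (tab$partners_sp1 == n & tab$partners_sp2 == 0) |
    (tab$partners_sp1 == 0 & tab$partners_sp2 == 1)
  ok <- all(ok_patch)
  tab$ok <- ok_patch
  rule_report("multiplicity", ok,
              predicted_azeotrope = if (ok) c(1 / (n + 1), n / (n + 1)),
              multiplicity_n = as.integer(n),
              n_species = 2L, details = tab)
}

#' Check the fully connected bond condition
#'
#' Satisfied when every patch has exactly one bonding partner on every
#' species.  The mixture is then azeotropic at every composition: the
#' coexisting phases keep the parent concentration throughout demixing.
#'
#' @param mixture a [mixture_spec()].
#' @return a `rule_report` whose `predicted_azeotrope` is the marker `"all"`.
#' @export
check_fully_connected <- function(mixture) {
  tab <- patch_partner_table(mixture)
  cnt <- as.matrix(tab[, grep("^partners_sp", names(tab)), drop = FALSE])
  ok <- all(cnt == 1)
  rule_report("fully_connected", ok,
              predicted_azeotrope = if (ok) "all",
              m = mixture$n_species, n_species = mixture$n_species,
              details = tab)
}

#' Common unbonded probability at the azeotrope
#'
#' At the azeotropic composition the full law of mass action collapses to a
#' single scalar quadratic for the common unbonded probability X:
#' `X = 1 / (1 + w rho Delta X)` with weight `w = m/N_s` for exclusivity
#' (m bonding partners per patch, m = 1 in the strict rule), `w = n/(n+1)`
#' for the n-fold multiplicity rule, and `w = 1` for the fully connected
#' rule (at every composition).
#'
#' @param rule a satisfied `rule_report`.
#' @param phi total packing fraction.
#' @param delta_bond bond integral Delta (units sigma^3).
#' @param sigma particle diameter (defines the particle volume).
#' @return the physical root X in (0, 1].
#' @export
solve_azeotropic_x <- function(rule, phi, delta_bond, sigma = 1) {
  if (!rule$satisfied) stop("rule is not satisfied; no azeotropic solution")
  stopifnot(phi >= 0, delta_bond >= 0)
  w <- switch(rule$rule,
              exclusivity = rule$m / rule$n_species,
              multiplicity = rule$multiplicity_n / (rule$multiplicity_n + 1),
              fully_connected = 1,
              stop("unknown rule"))
  rho <- phi / (pi * sigma^3 / 6)
  cc <- w * rho * delta_bond
  if (cc == 0) return(1)
  x <- (-1 + sqrt(1 + 4 * cc)) / (2 * cc)
  if (!(x > 0 && x <= 1 + 1e-12))
    stop("no physical root in (0, 1]")  # unreachable for valid inputs
  min(x, 1)
}
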