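#' Apparent Ca2+ dissociation constants for common chelators
#'
#' Single-site apparent dissociation constants (mol/L) for Ca2+ binding to
#' EGTA, BAPTA and 5,5'-dibromo-BAPTA at pH 7.4, ~22 C and physiological
#' ionic strength (~0.1-0.25 M), as used for recording-solution design.
#' Apparent Kd values are condition dependent; these are frozen, documented
#' defaults in the range of the standard chelator literature and can be
#' overridden per \code{\link{chelator_spec}}.
#'
#' @return data.frame with columns \code{name} and \code{kd_ca} (mol/L).
#' @export
#' @examples
#' chelator_constants()
chelator_constants <- function() {
  data.frame(
    name  = c("egta", "bapta", "dibromo_bapta"),
    kd_ca = c(150e-9, 220e-9, 1.6e-6),
    stringsAsFactors = FALSE
  )
}

#' Define a Ca2+ chelator at a given total concentration
#'
#' @param name chelator label. If \code{kd_ca} is omitted the name is looked
#'   up (case-insensitively) in \code{\link{chelator_constants}}.
#' @param total_conc total chelator concentration, mol/L (>= 0).
#' @param kd_ca apparent Ca2+ dissociation constant, mol/L (> 0).
#' @return object of class \code{chelator_spec}.
#' @export
#' @examples
#' chelator_spec("egta", 1e-3)
#' chelator_spec("fast_buffer", 5e-4, kd_ca = 2.2e-7)
chelator_spec <- function(name, total_conc, kd_ca = NULL) {
  if (is.null(kd_ca)) {
    tab <- chelator_constants()
    i <- match(tolower(name), tab$name)
    if (is.na(i)) {
      stop("unknown chelator '", name, "'; supply kd_ca explicitly", call. = FALSE)
    }
    kd_ca <- tab$kd_ca[i]
  }
  if (!is.finite(total_conc) || total_conc < 0) {
    stop("total_conc must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(kd_ca) || kd_ca <= 0) {
    stop("kd_ca must be finite and > 0", call. = FALSE)
  }
  structure(
    list(name = as.character(name), total_conc = total_conc, kd_ca = kd_ca),
    class = "chelator_spec"
  )
}

#' Define a buffered Ca2+ solution
#'
#' A mixture of chelators plus a total Ca2+ content; the free Ca2+
#' concentration follows from single-metal 1:1 binding equilibria
#' (\code{\link{free_ca}}). pH and temperature are carried as metadata only:
#' their effect is absorbed into the apparent Kd values.
#'
#' @param chelators list of \code{\link{chelator_spec}} objects (may be empty).
#' @param total_ca total Ca2+, mol/L (>= 0); may be \code{NA} when the system
#'   is only used with \code{\link{total_ca_for_free}}.
#' @param pH,temperature metadata (unitless / K).
#' @return object of class \code{buffer_system}.
#' @export
#' @examples
#' sys <- buffer_system(list(chelator_spec("egta", 1e-3)), total_ca = 5e-4)
#' free_ca(sys)
buffer_system <- function(chelators = list(), total_ca = NA_real_,
                          pH = 7.4, temperature = 295.15) {
  if (inherits(chelators, "chelator_spec")) chelators <- list(chelators)
  stopifnot(is.list(chelators))
  for (ch in chelators) {
    if (!inherits(ch, "chelator_spec")) {
      stop("all chelators must be chelator_spec objects", call. = FALSE)
    }
  }
  nm <- vapply(chelators, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("chelator names must be unique", call. = FALSE)
  if (!is.na(total_ca) && (!is.finite(total_ca) || total_ca < 0)) {
    stop("total_ca must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(chelators = chelators, total_ca = total_ca,
         pH = pH, temperature = temperature),
    class = "buffer_system"
  )
}

# conservation residual: free + bound(free) - total
ca_conservation <- function(free, totals, kds, total_ca) {
  free + sum(totals * free / (free + kds)) - total_ca
}

#' Free Ca2+ concentration of a buffered solution
#'
#' Solves the Ca2+ conservation equation
#' \deqn{[Ca]_{tot} = c + \sum_i B_i \, c / (c + K_{d,i})}
#' for the free concentration \eqn{c}. The left-hand side is strictly
#' increasing in \eqn{c}, so the root on \eqn{[0, [Ca]_{tot}]} is unique; it
#' is bracketed by \code{\link[stats]{uniroot}} and polished by Newton steps
#' to a relative tolerance below 1e-12.
#'
#' @param system a \code{\link{buffer_system}} with finite \code{total_ca}.
#' @return free Ca2+ concentration, mol/L.
#' @export
#' @examples
#' free_ca(buffer_system(list(chelator_spec("egta", 1e-3)), total_ca = 3e-4))
free_ca <- function(system) {
  stopifnot(inherits(system, "buffer_system"))
  total_ca <- system$total_ca
  if (!is.finite(total_ca) || total_ca < 0) {
    stop("system must have a finite non-negative total_ca", call. = FALSE)
  }
  if (total_ca == 0) return(0)
  totals <- vapply(system$chelators, `[[`, numeric(1), "total_conc")
  kds    <- vapply(system$chelators, `[[`, numeric(1), "kd_ca")
  if (length(totals) == 0 || all(totals == 0)) return(total_ca)

  f <- function(c) ca_conservation(c, totals, kds, total_ca)
  root <- stats::uniroot(f, lower = 0, upper = total_ca,
                         tol = max(1e-30, total_ca * 1e-14))$root
  # Newton polish: f'(c) = 1 + sum(B*Kd/(c+Kd)^2)
  for (i in 1:3) {
    fp <- 1 + sum(totals * kds / (root + kds)^2)
    step <- f(root) / fp
    root <- min(max(root - step, 0), total_ca)
  }
  root
}

#' Total Ca2+ required for a target free Ca2+ concentration
#'
#' Closed-form inverse of \code{\link{free_ca}}:
#' \deqn{[Ca]_{tot} = c_{free} \left(1 + \sum_i B_i/(c_{free}+K_{d,i})\right)}
#' This is the calculation behind designing recording solutions of stated
#' free Ca2+ (e.g. 70 or 140 nM in 1 mM EGTA).
#'
#' @param system a \code{\link{buffer_system}}; its \code{total_ca} is ignored.
#' @param target_free desired free Ca2+, mol/L (>= 0).
#' @return total Ca2+ to add, mol/L.
#' @export
#' @examples
#' sys <- buffer_system(list(chelator_spec("egta", 1e-3)))
#' tot <- total_ca_for_free(sys, 140e-9)
#' free_ca(buffer_system(sys$chelators, total_ca = tot))  # 1.4e-7
total_ca_for_free <- function(system, target_free) {
  stopifnot(inherits(system, "buffer_system"))
  if (!is.finite(target_free) || target_free < 0) {
    stop("target_free must be finite and >= 0", call. = FALSE)
  }
  if (target_free == 0) return(0)
  totals <- vapply(system$chelators, `[[`, numeric(1), "total_conc")
  kds    <- vapply(system$chelators, `[[`, numeric(1), "kd_ca")
  target_free * (1 + sum(totals / (target_free + kds)))
}

#' Batch total/free Ca2+ conversion
#'
#' Applies \code{\link{total_ca_for_free}} row-wise to a table of target free
#' Ca2+ concentrations under a common chelator mixture, the batch workflow
#' used when planning a series of recording solutions.
#'
#' @param targets data.frame with a \code{target_free} column (mol/L).
#' @param system a \code{\link{buffer_system}} describing the chelators.
#' @return the input with a \code{computed_total} column appended.
#' @export
ca_solution_table <- function(targets, system) {
  stopifnot(is.data.frame(targets), "target_free" %in% names(targets))
  targets$computed_total <- vapply(
    targets$target_free, function(x) total_ca_for_free(system, x), numeric(1))
  targets
}
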