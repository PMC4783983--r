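# ---------------------------------------------------------------------------
# Atom selection mini-language
#
# Grammar (case-insensitive keywords):
#   expr     := or_expr
#   or_expr  := and_expr ('or' and_expr)*
#   and_expr := not_expr ('and' not_expr)*
#   not_expr := 'not' not_expr | primary
#   primary  := '(' expr ')' | term
#   term     := 'name' IDENT+ | 'resid' RANGE+ | 'mainchain' | 'sidechain'
#             | 'solute' | 'solvent' | 'hydrogen' | 'heavy' | 'all'
# RANGE is an integer or a:b. Multiple idents/ranges after name/resid are
# OR-ed together and terminate at the next keyword or parenthesis.
# ---------------------------------------------------------------------------

.sel_keywords <- c("and", "or", "not", "name", "resid", "mainchain",
                   "sidechain", "solute", "solvent", "hydrogen", "heavy",
                   "all", "(", ")")

#' Select atoms with a small expression language
#'
#' Supports `name <atom names>`, `resid <i>` / `resid <a>:<b>`,
#' `mainchain`, `sidechain`, `solute`, `solvent`, `hydrogen`, `heavy` and
#' `all`, composable with `and`, `or`, `not` and parentheses. Examples:
#' `"name CA and solute"`, `"not solvent"`, `"resid 5:20 and heavy"`.
#'
#' @param sys An [sd_system()].
#' @param expression Selection string.
#' @return Sorted integer vector of 1-based atom indices. An empty result
#'   is returned with a warning, not an error.
#' @export
select_atoms <- function(sys, expression) {
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_or(st, sys)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("selection syntax error near '%s'", st$toks[st$pos]))
  }
  idx <- which(mask)
  if (!length(idx)) warning("selection matched no atoms")
  idx
}

sel_tokenize <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "[[:space:],]+")[[1]]
  toks[nzchar(toks)]
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

sel_next <- function(st) {
  t <- sel_peek(st)
  st$pos <- st$pos + 1L
  t
}

sel_or <- function(st, sys) {
  m <- sel_and(st, sys)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "or") {
    sel_next(st)
    m <- m | sel_and(st, sys)
  }
  m
}

sel_and <- function(st, sys) {
  m <- sel_not(st, sys)
  while (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "and") {
    sel_next(st)
    m <- m & sel_not(st, sys)
  }
  m
}

sel_not <- function(st, sys) {
  if (!is.na(sel_peek(st)) && tolower(sel_peek(st)) == "not") {
    sel_next(st)
    return(!sel_not(st, sys))
  }
  sel_primary(st, sys)
}

sel_primary <- function(st, sys) {
  t <- sel_peek(st)
  if (is.na(t)) stop("selection syntax error: unexpected end of expression")
  if (t == "(") {
    sel_next(st)
    m <- sel_or(st, sys)
    if (!identical(sel_next(st), ")")) {
      stop("selection syntax error: missing closing parenthesis")
    }
    return(m)
  }
  sel_term(st, sys)
}

sel_args <- function(st) {
  args <- character(0)
  repeat {
    t <- sel_peek(st)
    if (is.na(t) || tolower(t) %in% .sel_keywords) break
    args <- c(args, sel_next(st))
  }
  if (!length(args)) stop("selection syntax error: keyword needs arguments")
  args
}

sel_term <- function(st, sys) {
  at <- sys$atoms
  kw <- tolower(sel_next(st))
  switch(kw,
    name = {
      at$name %in% toupper(sel_args(st))
    },
    resid = {
      args <- sel_args(st)
      m <- rep(FALSE, nrow(at))
      for (a in args) {
        if (grepl("^[0-9]+:[0-9]+$", a)) {
          r <- as.integer(strsplit(a, ":")[[1]])
          m <- m | (at$resid >= r[1] & at$resid <= r[2])
        } else if (grepl("^[0-9]+$", a)) {
          m <- m | at$resid == as.integer(a)
        } else {
          stop(sprintf("selection syntax error: bad resid '%s'", a))
        }
      }
      m
    },
    mainchain = at$is_mainchain,
    sidechain = at$is_solute & !at$is_mainchain,
    solute = at$is_solute,
    solvent = !at$is_solute,
    hydrogen = at$is_hydrogen,
    heavy = !at$is_hydrogen,
    all = rep(TRUE, nrow(at)),
    stop(sprintf("selection syntax error: unknown keyword '%s'", kw))
  )
}

#' Analysis configuration
#'
#' Bundles the geometric cutoffs and run parameters shared across modules.
#' Defaults: hydrogen-bond donor-acceptor distance 3.5 Angstrom and
#' donor-hydrogen-acceptor angle 120 degrees, native-contact cutoff 6
#' Angstrom (strict `<`), SASA probe 1.4 Angstrom with 960 test points per
#' atom, hydration-shell cutoff 4.5 Angstrom.
#'
#' @param hb_distance_cutoff Donor-acceptor distance cutoff (Angstrom).
#' @param hb_angle_cutoff Minimum donor-hydrogen-acceptor angle (degrees).
#' @param native_contact_cutoff Native-contact distance cutoff (Angstrom).
#' @param sasa_probe_radius Solvent probe radius (Angstrom).
#' @param sasa_points_per_atom Quadrature points per atom sphere.
#' @param hydration_cutoff Hydration-shell cutoff (Angstrom).
#' @param temperature Temperature in K.
#' @param random_seed Integer seed recorded in report manifests.
#' @return A list of class `sd_config`.
#' @export
analysis_config <- function(hb_distance_cutoff = 3.5, hb_angle_cutoff = 120,
                            native_contact_cutoff = 6.0,
                            sasa_probe_radius = 1.4,
                            sasa_points_per_atom = 960L,
                            hydration_cutoff = 4.5, temperature = 300,
                            random_seed = 1L) {
  stopifnot(hb_distance_cutoff > 0, hb_angle_cutoff > 0,
            hb_angle_cutoff <= 180, native_contact_cutoff > 0,
            sasa_probe_radius > 0, sasa_points_per_atom >= 60,
            hydration_cutoff > 0, temperature > 0)
  structure(list(hb_distance_cutoff = hb_distance_cutoff,
                 hb_angle_cutoff = hb_angle_cutoff,
                 native_contact_cutoff = native_contact_cutoff,
                 sasa_probe_radius = sasa_probe_radius,
                 sasa_points_per_atom = as.integer(sasa_points_per_atom),
                 hydration_cutoff = hydration_cutoff,
                 temperature = temperature,
                 random_seed = as.integer(random_seed)),
            class = "sd_config")
}
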