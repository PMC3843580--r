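# Reading and writing metabolic models in the column-based tab-separated
# reaction-list format (BiGG-style reaction equations). One reactions file is
# mandatory; optional metabolite / description files only add display names.

#' Parse a reaction equation string
#'
#' Dialect: an optional `"[c] :"` prefix sets a default compartment for bare
#' metabolite tokens; terms are `met` or `(2.5) met`, joined by `+`; the arrow
#' is `-->` (irreversible), `<==>` (reversible) or `<--` (irreversible with
#' sides swapped); a per-metabolite `[x]` suffix overrides the default
#' compartment; an empty side denotes an exchange/demand reaction. Left-side
#' coefficients are negated; a metabolite appearing on both sides is summed.
#'
#' @param text equation text, e.g. `"[c] : a + (2) b --> c"`.
#' @return a `reaction_equation`: list with `stoich` (named signed numeric),
#'   `reversible` flag and `default_compartment`.
#' @examples
#' parse_reaction_equation("glc[e] <==> glc[c]")$stoich
#' parse_reaction_equation("a[e] <==>")$stoich  # exchange form
#' @export
parse_reaction_equation <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    fk_format_error("empty reaction equation")
  }
  eq <- trimws(text)
  dc <- NA_character_
  pref <- regmatches(eq, regexec("^\\[([A-Za-z0-9]+)\\]\\s*:\\s*", eq))[[1]]
  if (length(pref)) {
    dc <- pref[2]
    eq <- sub("^\\[([A-Za-z0-9]+)\\]\\s*:\\s*", "", eq)
  }
  arrow <- if (grepl("<==>", eq, fixed = TRUE)) "<==>"
           else if (grepl("-->", eq, fixed = TRUE)) "-->"
           else if (grepl("<--", eq, fixed = TRUE)) "<--"
           else fk_format_error(paste0("missing reaction arrow in '", text, "'"))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2) fk_format_error(paste0("more than one arrow in '", text, "'"))
  left <- if (length(sides) >= 1) sides[1] else ""
  right <- if (length(sides) == 2) sides[2] else ""
  if (arrow == "<--") { tmp <- left; left <- right; right <- tmp }
  reversible <- arrow == "<==>"

  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    coefs <- numeric(0)
    for (term in terms) {
      if (!nzchar(term)) fk_format_error(paste0("empty term in '", text, "'"))
      coef <- 1
      met <- term
      cm <- regmatches(term, regexec("^\\(\\s*([-0-9.eE]+)\\s*\\)\\s*(.*)$", term))[[1]]
      if (length(cm)) {
        coef <- suppressWarnings(as.numeric(cm[2]))
        met <- trimws(cm[3])
      }
      if (is.na(coef)) fk_format_error(paste0("malformed coefficient in term '", term, "'"))
      if (coef == 0) fk_format_error(paste0("zero coefficient in term '", term, "'"))
      if (!grepl("^[A-Za-z0-9_.:-]+(\\[[A-Za-z0-9]+\\])?$", met)) {
        fk_format_error(paste0("malformed metabolite token '", met, "' in '", text, "'"))
      }
      if (!grepl("\\[[A-Za-z0-9]+\\]$", met) && !is.na(dc)) {
        met <- paste0(met, "[", dc, "]")
      }
      coefs[met] <- (if (met %in% names(coefs)) coefs[[met]] else 0) + coef
    }
    coefs
  }
  l <- parse_side(left)
  r <- parse_side(right)
  if (length(l) == 0 && length(r) == 0) {
    fk_format_error(paste0("reaction equation has no metabolites: '", text, "'"))
  }
  st <- stats::setNames(numeric(0), character(0))
  for (met in names(l)) st[met] <- -l[[met]]
  for (met in names(r)) st[met] <- (if (met %in% names(st)) st[[met]] else 0) + r[[met]]
  st <- st[st != 0]
  structure(list(stoich = st, reversible = reversible, default_compartment = dc),
            class = "reaction_equation")
}

# shortest decimal rendering that parses back to the identical double
fmt_num <- function(x) {
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) return("")
    if (!is.finite(v)) return(if (v > 0) "Inf" else "-Inf")
    for (d in 1:17) {
      s <- format(v, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

tsv_required <- c("abbreviation", "equation")
tsv_known <- c("abbreviation", "name", "equation", "lowbnd", "uppbnd",
               "obj_coef", "rule", "subsystem")

#' Read a metabolic model from a tab-separated reaction list
#'
#' The reactions file must have a header row; column names are matched
#' case-insensitively. Required columns: `abbreviation`, `equation`.
#' Recognised optional columns: `name`, `lowbnd`, `uppbnd`, `obj_coef`,
#' `rule`, `subsystem`. Missing bound cells default by the equation's arrow:
#' `[-1000, 1000]` for `<==>`, `[0, 1000]` otherwise. Unknown columns are
#' carried along and written back by [write_tsv_model()]. Lines starting with
#' `#` are skipped.
#'
#' @param react_path path to the reactions file.
#' @param desc_path optional description file (`key<TAB>value` rows; key
#'   `id` or `name` sets the model id).
#' @param met_path optional metabolite file with columns `abbreviation`,
#'   `name` adding metabolite display names.
#' @return a [MetabolicModel].
#' @export
read_tsv_model <- function(react_path, desc_path = NULL, met_path = NULL) {
  if (!file.exists(react_path)) {
    fk_usage_error(paste0("model file not found: ", react_path))
  }
  df <- utils::read.delim(react_path, sep = "\t", quote = "\"", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(tsv_required, names(df))
  if (length(miss)) {
    fk_format_error(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$abbreviation)) {
    fk_identifier_error(paste0("duplicate abbreviation(s): ",
      paste(unique(df$abbreviation[duplicated(df$abbreviation)]), collapse = ", ")))
  }
  n <- nrow(df)
  eqs <- lapply(df$equation, parse_reaction_equation)

  num_col <- function(col, default_fun) {
    if (!col %in% names(df)) return(vapply(seq_len(n), default_fun, numeric(1)))
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad)) {
      fk_format_error(sprintf("non-numeric %s value '%s' for '%s'",
                              col, df[[col]][bad[1]], df$abbreviation[bad[1]]))
    }
    ifelse(is.na(v), vapply(seq_len(n), default_fun, numeric(1)), v)
  }
  lb <- num_col("lowbnd", function(i) if (eqs[[i]]$reversible) -1000 else 0)
  ub <- num_col("uppbnd", function(i) 1000)
  obj <- num_col("obj_coef", function(i) 0)
  rule <- if ("rule" %in% names(df)) ifelse(is.na(df$rule), "", df$rule) else rep("", n)
  subsystem <- if ("subsystem" %in% names(df)) df$subsystem else rep(NA_character_, n)
  rxn_name <- if ("name" %in% names(df)) df$name else rep(NA_character_, n)

  mets <- unique(unlist(lapply(eqs, function(e) names(e$stoich))))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    st <- eqs[[j]]$stoich
    ii <- c(ii, match(names(st), mets))
    jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(length(mets), n))

  extra_cols <- setdiff(names(df), tsv_known)
  extra <- if (length(extra_cols)) df[, extra_cols, drop = FALSE] else data.frame()

  model_id <- sub("\\.[^.]*$", "", basename(react_path))
  met_name <- rep(NA_character_, length(mets))
  if (!is.null(desc_path)) {
    dd <- utils::read.delim(desc_path, sep = "\t", comment.char = "#", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character",
                            check.names = FALSE)
    names(dd) <- tolower(names(dd))
    if (all(c("key", "value") %in% names(dd))) {
      hit <- dd$value[dd$key %in% c("id", "name")]
      if (length(hit)) model_id <- hit[1]
    }
  }
  if (!is.null(met_path)) {
    md <- utils::read.delim(met_path, sep = "\t", comment.char = "#", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character",
                            check.names = FALSE)
    names(md) <- tolower(names(md))
    if (all(c("abbreviation", "name") %in% names(md))) {
      met_name <- md$name[match(mets, md$abbreviation)]
    }
  }

  metabolic_model(model_id = model_id, S = S, metabolites = mets,
                  reactions = df$abbreviation,
                  lower_bound = lb, upper_bound = ub, objective_coef = obj,
                  gpr = rule, subsystem = subsystem, reaction_name = rxn_name,
                  metabolite_name = met_name, extra = extra)
}

render_equation <- function(model, j) {
  col <- model@S[, j]
  nz <- which(col != 0)
  lhs <- nz[col[nz] < 0]
  rhs <- nz[col[nz] > 0]
  term <- function(i, coef) {
    k <- abs(coef)
    if (k == 1) model@metabolites[i] else paste0("(", fmt_num(k), ") ", model@metabolites[i])
  }
  left <- paste(vapply(lhs, function(i) term(i, col[i]), character(1)), collapse = " + ")
  right <- paste(vapply(rhs, function(i) term(i, col[i]), character(1)), collapse = " + ")
  arrow <- if (model@lower_bound[j] < 0) "<==>" else "-->"
  trimws(paste(left, arrow, right))
}

#' Write a metabolic model as a tab-separated reaction list
#'
#' Emits the dialect read by [read_tsv_model()]: reading the written file
#' reproduces the model (identifiers, stoichiometry, bounds, objective and
#' canonical rule text). Numbers are written as the shortest decimal that
#' parses back to the identical value; coefficients are wrapped as `"(k)"`
#' only when `k != 1`.
#'
#' @param model a [MetabolicModel].
#' @param react_path output path.
#' @return `invisible(react_path)`.
#' @export
write_tsv_model <- function(model, react_path) {
  n <- length(model@reactions)
  df <- data.frame(
    abbreviation = model@reactions,
    name = model@reaction_name,
    equation = vapply(seq_len(n), function(j) render_equation(model, j), character(1)),
    lowbnd = fmt_num(model@lower_bound),
    uppbnd = fmt_num(model@upper_bound),
    obj_coef = fmt_num(model@objective_coef),
    rule = model@gpr_text,
    subsystem = model@subsystem,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (nrow(model@extra) == n && ncol(model@extra) > 0) df <- cbind(df, model@extra)
  con <- file(react_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(react_path)
}

#' SBML import placeholder
#'
#' SBML parsing is delegated to a dedicated companion package and is not part
#' of this toolkit; this stub exists so scripts fail with a clear message.
#'
#' @param path ignored.
#' @export
read_sbml_model <- function(path) {
  fk_capability_error("SBML input is not supported by fluxkit; install the SBML companion package and convert to the TSV reaction-list format")
}
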