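#' Plain-text model and data formats
#'
#' Models, response tables and connection matrices round-trip through
#' delimited text so that runs are diffable and external (experimental)
#' response data can enter the pipeline at the response-table boundary.
#'
#' @name model_io
NULL

strip_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

split_terms <- function(expr) {
  strip_ws(strsplit(expr, "+", fixed = TRUE)[[1]])
}

# "2*X" -> list(coef, species); plain "X" -> coef 1; "a*X" -> weight slot
parse_term <- function(term) {
  if (grepl("*", term, fixed = TRUE)) {
    parts <- strip_ws(strsplit(term, "*", fixed = TRUE)[[1]])
    if (length(parts) != 2) stop_definition("cannot parse term '%s'", term)
    w <- suppressWarnings(as.numeric(parts[1]))
    list(weight = if (is.na(w)) parts[1] else w, species = parts[2])
  } else {
    list(weight = 1, species = term)
  }
}

#' Write a model definition file
#'
#' @param network an `mra_network`.
#' @param path output file path.
#' @param partition optional `mra_partition` (adds `modules`/`outputs`).
#' @param params optional named parameter vector (adds `params`).
#' @return `path`, invisibly.
#' @export
write_model <- function(network, path, partition = NULL, params = NULL) {
  ln <- c("# retromra model definition", paste("model:", network$name), "",
          "[species]")
  for (sp in network$species) {
    extra <- if (!is.null(sp$of)) paste0(" of=", paste(sp$of, collapse = ",")) else ""
    mod <- if (!is.na(sp$module)) paste0(" module=", sp$module) else ""
    ln <- c(ln, paste0(sp$name, " ", sp$role, extra, mod))
  }
  ln <- c(ln, "", "[reactions]")
  for (rx in network$reactions) {
    line <- format_reaction(rx)
    if (!is.null(rx$modifier)) {
      line <- paste0(line, " [modifier: ", rx$modifier$effector, ", ",
                     rx$modifier$u, ", ", rx$modifier$k, "]")
    }
    ln <- c(ln, line)
  }
  ln <- c(ln, "", "[totals]")
  for (law in network$conservation) {
    terms <- vapply(names(law$coef), function(s) {
      if (law$coef[[s]] == 1) s else paste0(law$coef[[s]], "*", s)
    }, "")
    ln <- c(ln, paste(law$total, "=", paste(terms, collapse = " + ")))
  }
  if (!is.null(partition)) {
    ln <- c(ln, "", "[modules]")
    for (m in partition$modules) {
      ln <- c(ln, paste0(m$name, ": ", paste(m$species, collapse = ", ")))
    }
    ln <- c(ln, "", "[outputs]")
    for (m in partition$modules) {
      terms <- vapply(m$output, function(t) {
        if (identical(t$weight, 1)) t$species else paste0(t$weight, "*", t$species)
      }, "")
      ln <- c(ln, paste(m$name, "=", paste(terms, collapse = " + ")))
    }
  }
  if (!is.null(params)) {
    ln <- c(ln, "", "[params]")
    ln <- c(ln, paste(names(params), "=",
                      vapply(unname(unlist(params)), format, "", digits = 17)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a model definition file
#'
#' @param path file written by [write_model()] (or hand-authored in the
#'   same format).
#' @return list with `network`, `partition` (or `NULL`), `params` (or
#'   `NULL`).
#' @export
read_model <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- strip_ws(sub("#.*$", "", raw))
  name <- "model"
  section <- NA_character_
  sp <- list(); rx <- list(); laws <- list()
  modules <- list(); outputs <- list(); params <- c()
  for (line in raw) {
    if (!nzchar(line)) next
    if (grepl("^model:", line)) { name <- strip_ws(sub("^model:", "", line)); next }
    m <- regmatches(line, regexec("^\\[(\\w+)\\]$", line))[[1]]
    if (length(m)) { section <- m[2]; next }
    if (is.na(section)) stop_definition("content before any section: '%s'", line)
    switch(section,
      species = {
        tok <- strsplit(line, "\\s+")[[1]]
        of <- NULL; module <- NA_character_
        for (t in tok[-(1:2)]) {
          if (grepl("^of=", t)) of <- strsplit(sub("^of=", "", t), ",")[[1]]
          if (grepl("^module=", t)) module <- sub("^module=", "", t)
        }
        sp[[length(sp) + 1]] <- species(tok[1], tok[2], of = of, module = module)
      },
      reactions = {
        modifier <- NULL
        mm <- regmatches(line, regexec("\\[modifier:\\s*([^,]+),\\s*([^,]+),\\s*([^]]+)\\]", line))[[1]]
        if (length(mm)) {
          modifier <- regulatory_multiplier(strip_ws(mm[2]), strip_ws(mm[3]), strip_ws(mm[4]))
          line <- strip_ws(sub("\\[modifier:.*\\]", "", line))
        }
        parts <- strip_ws(strsplit(line, "@", fixed = TRUE)[[1]])
        if (length(parts) != 2) stop_definition("reaction line needs '@ rate': '%s'", line)
        sides <- strip_ws(strsplit(parts[1], "->", fixed = TRUE)[[1]])
        if (length(sides) != 2) stop_definition("reaction line needs '->': '%s'", line)
        rx[[length(rx) + 1]] <- reaction(split_terms(sides[1]),
                                         split_terms(sides[2]),
                                         parts[2], modifier = modifier)
      },
      totals = {
        parts <- strip_ws(strsplit(line, "=", fixed = TRUE)[[1]])
        terms <- lapply(split_terms(parts[2]), parse_term)
        coef <- stats::setNames(vapply(terms, function(t) as.numeric(t$weight), 0),
                                vapply(terms, `[[`, "", "species"))
        laws[[length(laws) + 1]] <- conservation_law(coef, parts[1])
      },
      modules = {
        parts <- strip_ws(strsplit(line, ":", fixed = TRUE)[[1]])
        modules[[parts[1]]] <- strip_ws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
      },
      outputs = {
        parts <- strip_ws(strsplit(line, "=", fixed = TRUE)[[1]])
        outputs[[parts[1]]] <- lapply(split_terms(parts[2]), parse_term)
      },
      params = {
        parts <- strip_ws(strsplit(line, "=", fixed = TRUE)[[1]])
        params[parts[1]] <- as.numeric(parts[2])
      },
      stop_definition("unknown section '[%s]'", section)
    )
  }
  network <- mra_network(sp, rx, laws, name = name)
  partition <- NULL
  if (length(modules)) {
    missing_out <- setdiff(names(modules), names(outputs))
    if (length(missing_out)) {
      stop_definition("modules without outputs: %s", paste(missing_out, collapse = ", "))
    }
    partition <- mra_partition(lapply(names(modules), function(nm) {
      module_def(nm, modules[[nm]], outputs[[nm]])
    }), network)
  }
  list(network = network, partition = partition,
       params = if (length(params)) params else NULL)
}

#' Write a response table as delimited text
#'
#' Header lines (prefixed `#`) carry the perturbation specs; the body is a
#' TSV with species in rows and conditions in columns.  This file is also
#' the entry point for experimental data: fill in measured concentrations
#' (absolute or in consistent arbitrary units per species) and read it
#' back with [read_response_table()].
#'
#' @param table an `mra_response_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  hdr <- c("# retromra response table",
           paste("# network:", table$network_name),
           paste("# observables:", paste(table$observables, collapse = " ")),
           vapply(table$specs, function(s) {
             paste("# spec:", s$parameter, s$magnitude, s$mode)
           }, ""))
  cols <- c(list(reference = table$reference),
            lapply(table$conditions, `[[`, "conc"))
  df <- data.frame(species = table$species,
                   do.call(cbind, lapply(cols, function(x) unname(x[table$species]))),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a response table from delimited text
#'
#' @param path file in the format of [write_response_table()].
#' @return an `mra_response_table` (without an attached parameter set;
#'   sufficient for [global_responses()] and everything downstream).
#' @export
read_response_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  hdr <- raw[grepl("^#", raw)]
  network_name <- strip_ws(sub("^# network:", "", hdr[grepl("^# network:", hdr)]))
  observables <- strsplit(strip_ws(sub("^# observables:", "",
                                       hdr[grepl("^# observables:", hdr)])), "\\s+")[[1]]
  specs <- lapply(hdr[grepl("^# spec:", hdr)], function(line) {
    tok <- strsplit(strip_ws(sub("^# spec:", "", line)), "\\s+")[[1]]
    perturbation_spec(tok[1], as.numeric(tok[2]), tok[3])
  })
  body <- raw[!grepl("^#", raw)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  species <- df$species
  getcol <- function(nm) stats::setNames(as.numeric(df[[nm]]), species)
  conditions <- list()
  for (s in specs) {
    sides <- if (s$mode == "central") c("+", "-") else "+"
    for (sd in sides) {
      id <- paste0(s$parameter, sd)
      if (!id %in% names(df)) stop_definition("missing condition column '%s'", id)
      conditions[[id]] <- list(parameter = s$parameter,
                               side = if (sd == "+") 1 else -1,
                               magnitude = s$magnitude, mode = s$mode,
                               conc = getcol(id))
    }
  }
  structure(list(network_name = network_name, species = species,
                 observables = observables, params = NULL, specs = specs,
                 reference = getcol("reference"), conditions = conditions),
            class = "mra_response_table")
}

#' Write a connection matrix with its structured report
#'
#' @param r an `mra_connection_matrix`.
#' @param path output path for the matrix (TSV); the report goes to
#'   `paste0(path, ".report.txt")`.
#' @param invariance optional result of [invariance_check()] to include
#'   per-row insulation verdicts.
#' @return `path`, invisibly.
#' @export
write_connection_matrix <- function(r, path, invariance = NULL) {
  utils::write.table(data.frame(module = rownames(r),
                                format(unclass(r), digits = 17, trim = TRUE),
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  asg <- attr(r, "assignment")
  rep_lines <- c("# retromra connection report")
  w <- attr(r, "weights")
  if (!is.null(w)) {
    rep_lines <- c(rep_lines, paste("weights:", paste(names(w), "=", signif(w, 12),
                                                      collapse = ", ")))
  }
  for (m in rownames(r)) {
    verdict <- if (!is.null(invariance)) {
      if (isTRUE(invariance$insulated[[m]])) "insulated" else "violated"
    } else "not-checked"
    rep_lines <- c(rep_lines,
                   sprintf("row %s: perturbations {%s}; residual %.3e; kappa %.3g; insulation %s",
                           m, paste(asg[[m]], collapse = ", "),
                           attr(r, "residuals")[m], attr(r, "kappa")[m], verdict))
  }
  if (!is.null(invariance)) {
    rep_lines <- c(rep_lines,
                   sprintf("max discrepancy across assignments: %.3e (tolerance %.1e)",
                           max(invariance$discrepancy), invariance$tolerance))
  }
  writeLines(rep_lines, paste0(path, ".report.txt"))
  invisible(path)
}
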