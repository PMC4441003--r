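# GO concept dictionaries (original and rule-enhanced) and the protein
# lexicon. Surfaces are normalized (lowercased, tokenized, single-spaced) at
# build time; matching downstream is therefore case-insensitive.

#' Configure the synonym-generation rules
#'
#' The enhanced dictionary is the original dictionary plus rule-generated
#' synonyms. Two rule families are anchored to well-understood GO naming
#' patterns:
#' \describe{
#'   \item{M (metabolic family)}{"X metabolic process" yields "X metabolism"
#'     and "metabolism of X". The optional extensions handle
#'     "X biosynthetic process" -> \{"X biosynthesis", "biosynthesis of X"\}
#'     and "X catabolic process" -> \{"X catabolism", "catabolism of X"\}.}
#'   \item{P (positive regulation)}{"positive regulation of X" yields
#'     "stimulation of X", "X stimulation" and "pro-X"; when X has an entry
#'     in the variant table (e.g. apoptosis -> apoptotic) each form is also
#'     emitted with the variant substituted, giving e.g. "apoptotic
#'     stimulation" and "pro-apoptotic".}
#'   \item{N (negative analog)}{"negative regulation of X" yields
#'     "inhibition of X" and "anti-X" (plus variant substitutions). Off by
#'     default.}
#' }
#'
#' @param metabolic Apply rule M to "X metabolic process" names.
#' @param biosynthetic,catabolic Rule-M extensions, off by default.
#' @param positive_regulation Apply rule P.
#' @param negative_regulation Apply rule N, off by default.
#' @return A named list of class `rule_config`.
#' @export
rule_config <- function(metabolic = TRUE, biosynthetic = FALSE,
                        catabolic = FALSE, positive_regulation = TRUE,
                        negative_regulation = FALSE) {
  structure(list(metabolic = metabolic, biosynthetic = biosynthetic,
                 catabolic = catabolic,
                 positive_regulation = positive_regulation,
                 negative_regulation = negative_regulation),
            class = "rule_config")
}

#' Default noun-to-adjective variant table
#'
#' Derivational variants substituted into rule-generated synonyms (rule P/N).
#' User-extensible: bind extra rows with the same columns.
#'
#' @return A tibble with columns `noun` and `variant`.
#' @export
default_variant_table <- function() {
  tibble(
    noun = c("apoptosis", "proliferation", "inflammation"),
    variant = c("apoptotic", "proliferative", "inflammatory")
  )
}

#' Generate rule-based synonym variants for term names
#'
#' Applies the synonym-generation rules (see [rule_config()]) to term names.
#' Names that match no rule pattern yield no rows.
#'
#' @param names Character vector of term names.
#' @param variants A variant table ([default_variant_table()] format).
#' @param rules A [rule_config()].
#' @return A tibble with columns `name` (the input name), `surface`
#'   (normalized generated synonym) and `rule` ("M", "P" or "N").
#' @export
#' @examples
#' enhancement_variants("cyanophycin metabolic process")
#' enhancement_variants("positive regulation of apoptosis")
enhancement_variants <- function(names, variants = default_variant_table(),
                                 rules = rule_config()) {
  stopifnot(inherits(rules, "rule_config"))
  pair_rules <- list(
    list(on = rules$metabolic, suffix = " metabolic process",
         noun = "metabolism", rule = "M"),
    list(on = rules$biosynthetic, suffix = " biosynthetic process",
         noun = "biosynthesis", rule = "M"),
    list(on = rules$catabolic, suffix = " catabolic process",
         noun = "catabolism", rule = "M")
  )
  out <- list()
  for (nm in unique(names)) {
    low <- tolower(nm)
    for (pr in pair_rules) {
      if (!pr$on || !endsWith(low, pr$suffix)) next
      x <- substr(low, 1L, nchar(low) - nchar(pr$suffix))
      out[[length(out) + 1L]] <- tibble(
        name = nm,
        surface = c(paste(x, pr$noun), paste(pr$noun, "of", x)),
        rule = pr$rule
      )
    }
    reg <- function(prefix, forms_fn, rule_id, on) {
      if (!on || !startsWith(low, prefix)) return()
      x <- substring(low, nchar(prefix) + 1L)
      xs <- c(x, variants$variant[variants$noun == x])
      out[[length(out) + 1L]] <<- tibble(
        name = nm,
        surface = unlist(lapply(xs, forms_fn), use.names = FALSE),
        rule = rule_id
      )
    }
    reg("positive regulation of ",
        function(x) c(paste("stimulation of", x), paste(x, "stimulation"),
                      paste0("pro-", x)),
        "P", rules$positive_regulation)
    reg("negative regulation of ",
        function(x) c(paste("inhibition of", x), paste0("anti-", x)),
        "N", rules$negative_regulation)
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(name = character(), surface = character(), rule = character()))
  }
  res |>
    mutate(surface = normalize_surface(.data$surface)) |>
    distinct()
}

#' Build a GO concept dictionary
#'
#' The *original* dictionary contains every non-obsolete term's name and
#' synonyms, lowercased/normalized; any name or synonym ending in the word
#' "activity" additionally contributes the form with that trailing word
#' removed (provenance `activity_stripped`). The *enhanced* dictionary is
#' the original plus rule-generated synonyms (provenance `rule:M`, `rule:P`,
#' `rule:N`); it is always a superset of the original.
#'
#' @param ontology A `go_ontology`.
#' @param flavor `"original"` or `"enhanced"`.
#' @param variants Variant table for rule substitutions (enhanced only).
#' @param rules A [rule_config()] (enhanced only).
#' @return A `concept_dictionary`: a tibble with columns `surface`
#'   (normalized), `term_id` and `provenance`, with attribute `flavor`.
#' @export
build_go_dictionary <- function(ontology,
                                flavor = c("original", "enhanced"),
                                variants = default_variant_table(),
                                rules = rule_config()) {
  stopifnot(inherits(ontology, "go_ontology"))
  flavor <- match.arg(flavor)
  live <- ontology$terms[!ontology$terms$obsolete, ]

  base <- bind_rows(
    tibble(surface = live$name, term_id = live$id, provenance = "name"),
    ontology$synonyms |>
      filter(.data$id %in% live$id) |>
      transmute(surface = .data$synonym, term_id = .data$id,
                provenance = "synonym")
  )
  stripped <- base |>
    filter(str_detect(tolower(.data$surface), " activity$")) |>
    mutate(surface = str_replace(tolower(.data$surface), " activity$", ""),
           provenance = "activity_stripped")
  dict <- bind_rows(base, stripped) |>
    mutate(surface = normalize_surface(.data$surface)) |>
    filter(nzchar(.data$surface)) |>
    distinct()

  if (flavor == "enhanced") {
    gen <- enhancement_variants(live$name, variants = variants, rules = rules)
    if (nrow(gen)) {
      name_to_id <- setNames(live$id, live$name)
      gen <- gen |>
        transmute(surface = .data$surface,
                  term_id = unname(name_to_id[.data$name]),
                  provenance = paste0("rule:", .data$rule))
      dict <- bind_rows(dict, gen) |> distinct()
    }
  }
  structure(arrange(dict, .data$surface, .data$term_id),
            class = c("concept_dictionary", class(tibble())),
            flavor = flavor)
}

#' Read a protein lexicon from TSV
#'
#' A headerless two-column TSV mapping surface names to protein accessions.
#' One surface may map to several accessions (the ambiguity is preserved and
#' propagated to mentions); matching downstream is case-insensitive.
#'
#' @param path TSV path, columns surface and accession.
#' @return A `protein_lexicon`: tibble with normalized `surface` and
#'   `accession`.
#' @export
read_protein_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L |
                 !vapply(parts, function(p) all(nzchar(str_trim(p))), logical(1)))
  if (length(bad)) {
    abort(paste0("malformed protein lexicon line ", bad[1], ": ",
                 lines[bad[1]]))
  }
  tbl <- tibble(
    surface = normalize_surface(vapply(parts, `[`, "", 1L)),
    accession = str_trim(vapply(parts, `[`, "", 2L))
  ) |> distinct()
  structure(tbl, class = c("protein_lexicon", class(tibble())))
}

#' Write a concept dictionary to TSV for inspection
#'
#' Columns: surface, term_id, provenance.
#'
#' @param dictionary A `concept_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_tsv(as_tibble(dictionary), path, col_names = TRUE)
  invisible(path)
}
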