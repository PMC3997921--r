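# SMILES reader. Supports the organic subset, bracket atoms (isotope ignored,
# chirality stripped, explicit H counts, charges), branches, ring closures
# (including %nn), bond symbols - = # : / \ and dot-separated components.
# The same reader, in pattern mode, parses the restricted SMARTS dialect used
# by the key library: additionally `*` (any atom) and `~` (any bond); bracket
# charges become constraints instead of properties.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

parse_smiles_graph <- function(text, pattern = FALSE) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  atoms <- list()   # each: element, aromatic, charge, hcount, any, charge_set
  bonds <- list()   # each: begin, end, type ("1","2","3","ar","any","default")
  prev <- NA_integer_          # 0-based id of previous atom
  stack <- integer(0)
  pending <- NULL              # pending bond symbol
  ring <- list()               # closure number -> list(atom, type)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_,
                       any = FALSE, charge_set = FALSE) {
    id <- length(atoms)
    atoms[[id + 1]] <<- list(element = element, aromatic = aromatic,
                             charge = as.integer(charge), hcount = hcount,
                             any = any, charge_set = charge_set)
    if (!is.na(prev)) {
      type <- if (!is.null(pending)) pending else "default"
      bonds[[length(bonds) + 1]] <<- list(begin = prev, end = id, type = type)
    }
    pending <<- NULL
    prev <<- id
    invisible(id)
  }

  close_ring <- function(num) {
    if (is.na(prev)) stop("ring closure before any atom in: ", text, call. = FALSE)
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, type = pending)
      pending <<- NULL
    } else {
      open <- ring[[key]]
      ring[[key]] <<- NULL
      type <- if (!is.null(pending)) pending else if (!is.null(open$type)) open$type else "default"
      if (open$atom == prev) stop("ring closure bonds an atom to itself in: ", text, call. = FALSE)
      bonds[[length(bonds) + 1]] <<- list(begin = open$atom, end = prev, type = type)
      pending <<- NULL
    }
  }

  i <- 1
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (ch == "[") {
      j <- i + 1
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("unclosed bracket atom in: ", text, call. = FALSE)
      body <- paste0(chars[(i + 1):(j - 1)], collapse = "")
      a <- parse_bracket_atom(body, text, pattern)
      add_atom(a$element, a$aromatic, a$charge, a$hcount, a$any, a$charge_set)
      i <- j + 1
    } else if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); i <- i + 2
    } else if (ch %in% .organic_subset) {
      add_atom(ch, FALSE); i <- i + 1
    } else if (ch %in% .aromatic_organic) {
      add_atom(toupper(ch), TRUE); i <- i + 1
    } else if (ch == "*" && pattern) {
      add_atom(NA_character_, NA, any = TRUE); i <- i + 1
    } else if (ch == "-") { pending <- "1"; i <- i + 1
    } else if (ch == "=") { pending <- "2"; i <- i + 1
    } else if (ch == "#") { pending <- "3"; i <- i + 1
    } else if (ch == ":") { pending <- "ar"; i <- i + 1
    } else if (ch == "~" && pattern) { pending <- "any"; i <- i + 1
    } else if (ch %in% c("/", "\\")) { pending <- "1"; i <- i + 1   # stereo bond stripped
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in: ", text, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) stop("truncated %nn ring closure in: ", text, call. = FALSE)
      close_ring(as.integer(paste0(chars[i + 1], chars[i + 2]))); i <- i + 3
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1
    } else if (ch %in% c(" ", "\t")) {
      break   # trailing name field; handled by callers
    } else {
      stop("unexpected character '", ch, "' in: ", text, call. = FALSE)
    }
  }
  if (length(ring)) stop("unclosed ring bond in: ", text, call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in: ", text, call. = FALSE)
  if (!length(atoms)) stop("empty molecule: ", text, call. = FALSE)
  list(atoms = atoms, bonds = bonds)
}

parse_bracket_atom <- function(body, text, pattern) {
  rest <- body
  # isotope (ignored)
  rest <- sub("^[0-9]+", "", rest)
  any_atom <- FALSE
  aromatic <- FALSE
  element <- NA_character_
  if (grepl("^\\*", rest)) {
    if (!pattern) stop("wildcard atom outside pattern in: ", text, call. = FALSE)
    any_atom <- TRUE; aromatic <- NA
    rest <- sub("^\\*", "", rest)
  } else if (grepl("^#[0-9]+", rest)) {
    num <- as.integer(sub("^#([0-9]+).*$", "\\1", rest))
    map <- c(`5` = "B", `6` = "C", `7` = "N", `8` = "O", `15` = "P", `16` = "S",
             `9` = "F", `17` = "Cl", `35` = "Br", `53` = "I")
    element <- map[[as.character(num)]]
    if (is.null(element)) stop("unsupported atomic number in: ", text, call. = FALSE)
    aromatic <- NA   # pattern: either
    if (!pattern) stop("#n atom outside pattern in: ", text, call. = FALSE)
    rest <- sub("^#[0-9]+", "", rest)
  } else {
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", rest))
    if (!length(m) || !nzchar(m)) stop("cannot read bracket atom [", body, "] in: ", text, call. = FALSE)
    sym <- m   # bracket atoms are properly capitalised, so the greedy
               # two-letter match is the element symbol
    if (sym %in% c(.aromatic_organic, "se", "as")) {
      aromatic <- TRUE
      element <- toupper(substr(sym, 1, 1))
      if (sym == "se") element <- "Se"
      if (sym == "as") element <- "As"
    } else {
      element <- sym
    }
    rest <- sub(paste0("^", sym), "", rest)
  }
  # chirality stripped
  rest <- gsub("^@{1,2}(TH[12]|AL[12]|SP[1-3])?", "", rest)
  hcount <- NA_integer_
  if (grepl("^H", rest)) {
    rest <- sub("^H", "", rest)
    if (grepl("^[0-9]", rest)) {
      hcount <- as.integer(sub("^([0-9]+).*$", "\\1", rest))
      rest <- sub("^[0-9]+", "", rest)
    } else hcount <- 1L
  }
  charge <- 0L
  charge_set <- FALSE
  if (grepl("^\\+", rest)) {
    charge_set <- TRUE
    if (grepl("^\\+[0-9]", rest)) {
      charge <- as.integer(sub("^\\+([0-9]+).*$", "\\1", rest))
      rest <- sub("^\\+[0-9]+", "", rest)
    } else {
      charge <- nchar(sub("[^+].*$", "", rest))
      rest <- sub("^\\++", "", rest)
    }
  } else if (grepl("^-", rest)) {
    charge_set <- TRUE
    if (grepl("^-[0-9]", rest)) {
      charge <- -as.integer(sub("^-([0-9]+).*$", "\\1", rest))
      rest <- sub("^-[0-9]+", "", rest)
    } else {
      charge <- -nchar(sub("[^-].*$", "", rest))
      rest <- sub("^-+", "", rest)
    }
  }
  rest <- sub("^:[0-9]+", "", rest)   # atom map dropped
  if (nzchar(rest)) stop("unsupported bracket atom [", body, "] in: ", text, call. = FALSE)
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, any = any_atom, charge_set = charge_set)
}

# Convert the raw parse graph to a Structure (molecule semantics): resolve
# default bonds, build data frames. Pattern graphs stay in raw list form.
graph_to_structure <- function(g, name = "") {
  na <- length(g$atoms)
  atoms <- data.frame(
    element = vapply(g$atoms, function(a) a$element, ""),
    aromatic = vapply(g$atoms, function(a) isTRUE(a$aromatic), TRUE),
    charge = vapply(g$atoms, function(a) a$charge, 0L),
    hcount = vapply(g$atoms, function(a) a$hcount, NA_integer_),
    atom_id = 0:(na - 1),
    stringsAsFactors = FALSE
  )
  nb <- length(g$bonds)
  if (nb > 0) {
    type <- vapply(g$bonds, function(b) b$type, "")
    begin <- vapply(g$bonds, function(b) b$begin, 0L)
    end <- vapply(g$bonds, function(b) b$end, 0L)
    arom_pair <- atoms$aromatic[begin + 1] & atoms$aromatic[end + 1]
    aromatic <- type == "ar" | (type == "default" & arom_pair)
    order <- ifelse(type %in% c("2"), 2L, ifelse(type == "3", 3L, 1L))
    bonds <- data.frame(begin = begin, end = end, order = order,
                        aromatic = aromatic, bond_id = 0:(nb - 1),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(begin = integer(0), end = integer(0), order = integer(0),
                        aromatic = logical(0), bond_id = integer(0))
  }
  new_structure(atoms, bonds, name)
}

#' Parse a structure from SMILES or MOL text
#'
#' Accepts a SMILES string or a V2000 MOL block (auto-detected by the `V2000`
#' counts line). The result is standardized: aromaticity perceived, explicit
#' hydrogens folded into implicit counts, stereochemistry stripped.
#'
#' @param text SMILES string or MOL block.
#' @param name optional structure name (SMILES input only; MOL blocks carry
#'   their own title line).
#' @return a `Structure`.
#' @examples
#' benzene <- parse_structure("c1ccccc1")
#' n_atoms(benzene)
#' @export
parse_structure <- function(text, name = "") {
  stopifnot(is.character(text), length(text) == 1)
  if (grepl("V2000", text)) return(parse_molblock(text))
  s <- tryCatch(
    graph_to_structure(parse_smiles_graph(text), name),
    error = function(e) stop("failed to parse SMILES '", text, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  standardize(s, strip_salts = FALSE)
}

# V2000 MOL block reader (counts line, atom block, bond block).
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("MOL block too short", call. = FALSE)
  title <- trimws(lines[1])
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed V2000 counts line", call. = FALSE)
  if (na == 0) stop("empty molecule in MOL block", call. = FALSE)
  if (length(lines) < 4 + na + nb) stop("truncated MOL block", call. = FALSE)
  at <- lines[5:(4 + na)]
  element <- trimws(substr(at, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(at, 37, 39)))
  chg_code[is.na(chg_code)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[chg_code + 1L]
  atoms <- data.frame(element = element, aromatic = FALSE, charge = charge,
                      hcount = NA_integer_, atom_id = 0:(na - 1),
                      stringsAsFactors = FALSE)
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    b1 <- as.integer(substr(bl, 1, 3)); b2 <- as.integer(substr(bl, 4, 6))
    bt <- as.integer(substr(bl, 7, 9))
    if (any(is.na(b1) | is.na(b2) | is.na(bt))) stop("malformed bond block", call. = FALSE)
    aromatic <- bt == 4L
    order <- ifelse(aromatic, 1L, bt)
    if (any(!order %in% 1:3)) stop("unsupported bond type in MOL block", call. = FALSE)
    bonds <- data.frame(begin = b1 - 1L, end = b2 - 1L, order = order,
                        aromatic = aromatic, bond_id = 0:(nb - 1),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(begin = integer(0), end = integer(0), order = integer(0),
                        aromatic = logical(0), bond_id = integer(0))
  }
  # "M  CHG" property lines override the atom-block charge column
  for (ln in lines[grepl("^M  CHG", lines)]) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    cnt <- toks[1]
    for (k in seq_len(cnt)) {
      atoms$charge[toks[2 * k]] <- toks[2 * k + 1]
    }
  }
  standardize(new_structure(atoms, bonds, title), strip_salts = FALSE)
}
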