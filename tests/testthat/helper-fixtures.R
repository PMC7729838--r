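# Small in-code fixtures shared across tests.

# TransactionDB from a plain list of character vectors
tdbOf <- function(..., items = NULL) {
  TransactionDB(list(...), items = items)
}

# the 6-transaction toy set used for oracle-equivalence examples
toyTdb <- function() {
  tdbOf(c("A", "B", "C"), c("A", "B"), c("A", "C"), c("B", "C"), "A", "B")
}

# minimal catalog: two comorbidities plus the C34 index code
miniCatalog <- function() {
  diseaseCatalog(data.frame(
    icd10_code = c("I10", "J18"),
    category = c("hypertension", "pneumonia"),
    stringsAsFactors = FALSE))
}

# hand-built EMR record frame
recordFrame <- function(case_number, gender, age, hospital, icd10_codes) {
  data.frame(case_number = case_number, gender = gender, age = age,
             hospital = hospital, nationality = "Han", occupation = "Retired",
             marital_status = "Married", icd10_codes = icd10_codes,
             stringsAsFactors = FALSE)
}

# random small transaction set for property-style tests
randomTdb <- function(nItems, nTrans) {
  items <- LETTERS[seq_len(nItems)]
  sets <- lapply(seq_len(nTrans), function(i) {
    k <- sample(0:min(5, nItems), 1L)
    sort(sample(items, k))
  })
  TransactionDB(sets, items = items)
}

# igraph from an edge data.frame, for modularity tests
graphOf <- function(edges, vertices = NULL) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

# adjusted Rand index between two labelings (independent of any package)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  sumi <- sum(comb2(rowSums(tab)))
  sumj <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sumi * sumj / comb2(n)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
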