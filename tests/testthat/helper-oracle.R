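# Independent substructure-match oracle via RDKit (called through the
# python interpreter on PATH).  The oracle shares no code with the
# package's OpenBabel-based matcher: molecules are parsed, patterns
# compiled and unique matches counted by a different engine.

.oracleScript <- '
import sys, json
from rdkit import Chem
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
with open(sys.argv[1]) as fh:
    payload = json.load(fh)
mols = [Chem.MolFromSmiles(s) for s in payload["smiles"]]
pats = [Chem.MolFromSmarts(p) for p in payload["smarts"]]
out = []
for m in mols:
    if m is None:
        out.append(None)
        continue
    row = []
    for p in pats:
        if p is None:
            row.append(-1)
        else:
            row.append(len(m.GetSubstructMatches(p, uniquify=True)))
    out.append(row)
json.dump(out, open(sys.argv[2], "w"))
'

## Unique-match counts for each (molecule, pattern) pair, by RDKit.
oracleMatchCounts <- function(smiles, smarts) {
  script <- tempfile(fileext = ".py")
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(script, infile, outfile)))
  writeLines(.oracleScript, script)
  jsonlite::write_json(list(smiles = smiles, smarts = smarts), infile)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile)) {
    stop("RDKit oracle failed to run")
  }
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(res, function(row) {
    if (is.null(row)) rep(NA_integer_, length(smarts)) else
      as.integer(unlist(row))
  }))
  rownames(out) <- smiles
  out
}

## Fingerprint bits implied by oracle counts under the dictionary's
## count thresholds and removed-bit rule.
oracleFingerprint <- function(smiles, dict) {
  defs <- bitDefinitions(dict)
  counts <- oracleMatchCounts(smiles, defs$smarts)
  bits <- (counts >= matrix(defs$min_count, nrow(counts), 166,
                            byrow = TRUE)) * 1L
  bits[, defs$origin == "removed"] <- 0L
  colnames(bits) <- paste0("bit_", defs$index)
  bits
}

## The 50-molecule CHONS toy panel used for dual-engine checks.
toyPanel <- function() {
  c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "O=[N+]([O-])c1ccccc1", "O=Cc1ccccc1", "CC(=O)c1ccccc1",
    "OC(=O)c1ccccc1", "COC(=O)c1ccccc1", "NC(=O)c1ccccc1",
    "CNc1ccccc1", "CN(C)c1ccccc1", "c1ccncc1", "c1cc[nH]c1",
    "c1ccoc1", "c1ccsc1", "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1",
    "c1ccc2ccccc2c1", "c1ccc(-c2ccccc2)cc1", "C=Cc1ccccc1",
    "C#Cc1ccccc1", "COc1ccccc1", "Oc1ccccc1O", "Oc1ccc(O)cc1",
    "O=C1C=CC(=O)C=C1", "CC(=O)Nc1ccccc1", "N#Cc1ccccc1",
    "CSc1ccccc1", "NS(=O)(=O)c1ccccc1", "CS(C)=O", "CS(C)(=O)=O",
    "C1CCCCC1", "O=C1CCCCC1", "C1CCOC1", "C1COCCO1", "C1CCNCC1",
    "C1COCCN1", "O=C1CCCN1", "CCO", "CC(C)=O", "CC(N)=O",
    "NC(N)=O", "CN(C)C", "CCCCCC", "OCCCCCC", "C=CC=O",
    "C=CC(=O)OC", "C=CC=C", "C[N+](=O)[O-]")
}
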