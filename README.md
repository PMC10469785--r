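# bpdesign

Design and in-silico evaluation of **elongation-arrest blocking primers**
for host-DNA depletion in marker-gene metabarcoding.

## The problem

When the eukaryotic microbiota of a host-associated sample is profiled by
18S rRNA amplicon sequencing (e.g. the V9 hypervariable region amplified
with 1389F/1015R), the host's own 18S copies dominate the library and drown
out the organisms of interest. A standard countermeasure is a **blocking
primer**: an oligo that anneals to the host template *between* the two
amplification primers and carries a 3' **C3 spacer**
(1-dimethoxytrityloxy-propanediol-3-succinoyl chemistry), so the polymerase
can neither extend it nor read through it — host amplicons are arrested
while non-host templates amplify normally.

A useful blocking primer must satisfy three competing constraints:

* **anneal to the host** — it is taken from the host's amplicon interior,
  must map there uniquely, and must not overlap either amplification-primer
  footprint (elongation-arrest, not anneal-inhibition);
* **be long enough** — at least 20 nt of gene-specific sequence;
* **not anneal to anything else** — at least 3 mismatching nucleotides
  against every off-target (non-host eukaryote) sequence, counted under
  IUPAC base-set semantics on an ungapped sliding comparison over both
  strands.

`bpdesign` implements this design procedure end to end: degeneracy-aware
in-silico PCR, exhaustive candidate enumeration, host-uniqueness and
off-target specificity screening, rule-based validation of externally
supplied blockers (the packaged *Hermetia illucens* V9 blockers
BP-F_Hi_V9 and BP-R_Hi_V9 among them), and a deterministic mock-community
simulator that predicts, template by template, what amplifies and what is
arrested.

## Worked example

```r
library(bpdesign)

spec <- fixture_spec(seed = 42)           # synthetic 500 nt host, 120 nt interior
host <- make_host(spec)                   # embeds the 1389F/1015R binding sites
offt <- make_offtargets(host, spec)       # six off-targets at distances 3..8

design <- design_blocking_primers(host, bp_oligo("1389F"), bp_oligo("1015R"),
                                  offt, design_rules(), k = 2)
design
#> Blocking-primer design on 'host'
#>   amplicon [172,327), interior [187,307)
#>   2112 candidate window(s), 352 accepted, 6 off-target(s)
#>   emitted blocking primers:
#>     host:226-250:- (blocking): 5'-TACACAAACTCTGACTGCGTCACG[SpcC3]-3'
#>     host:226-250:+ (blocking): 5'-CGTGACGCAGTCAGAGTTTGTGTA[SpcC3]-3'
```

2112 windows of 20–30 nt (both orientations) fit inside the 120-nt
interior; 352 pass all rules — each is unique on the host and at least 3
mismatches from every off-target. The two emitted oligos are the top-ranked
window in both orientations, annotated with the C3 spacer.

```r
comm <- make_community(host, offt, spec)
simulate_community(comm$community, comm$host_ids,
                   bp_oligo("1389F"), bp_oligo("1015R"),
                   design$primers, t_block = 2)
#> Mock-community blocking report (20 templates, t_block = 2)
#>   amplified 9 | blocked 11 | no amplicon 0 (ambiguous 0)
#>   host suppression:    1.000
#>   collateral blocking: 0.000
```

Every host template is predicted arrested; no off-target is collaterally
blocked — by construction the off-targets sit ≥ 3 mismatches from every
accepted blocker while the binding threshold is 2.

Validating a published blocker against the same rules:

```r
amp <- design$amplicon
validate_blocking_primer(bp_oligo("BP-F_Hi_V9"), amp, host, offt)
#>   [ pass ] length                 23             (>= 20)
#>   [ FAIL ] host_locus             no host locus  (>= 1)
#>   ...
```

(The fly-specific blocker passes the length rule but of course does not map
to a random synthetic host.)

## Command line

```sh
bpdesign fixtures --out-dir bundle --seed 42
bpdesign design   --host bundle/host.fasta --offtargets bundle/offtargets.fasta \
                  --fwd 1389F --rev 1015R --out-dir out
bpdesign validate --oligo BP-F_Hi_V9 --host bundle/host.fasta \
                  --fwd 1389F --rev 1015R --out-dir val
bpdesign simulate --community bundle/community.fasta --host-ids bundle/host_ids.txt \
                  --blockers out/blocking_primers.fasta --fwd 1389F --rev 1015R \
                  --t-block 2 --out-dir sim
```

The script lives at `inst/exec/bpdesign` (installed under
`system.file("exec", "bpdesign", package = "bpdesign")`); `bp_cli()` exposes
the same interface from R. Rules come from flags or a YAML config
(flag > config > default); results go to files, logs to stderr; exit codes
are 0 (success), 1 (bad input), 2 (rule failure under `--strict`).

Candidate TSV column order: `host_id, start, end, strand, seq, gc_fraction,
host_copy_count, min_offtarget_mismatches, status, reject_reasons, rank`.
All coordinates are 0-based half-open on the plus strand.

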