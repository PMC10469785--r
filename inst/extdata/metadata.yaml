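# Fixture-table metadata. The real Hermetia illucens 18S rRNA reference the
# blocking primers target is recorded for provenance only; it is never
# fetched by the package or its tests.
oligo_table_version: 1
host_reference_accession: XR_005250514
host_organism: Hermetia illucens (black soldier fly)
marker: 18S rRNA V9 hypervariable region
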