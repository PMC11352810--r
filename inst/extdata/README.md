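# Bundled configuration files

`drug_dictionary.csv` — ingredient/brand name variants for the three
CDK4/6 inhibitors, used for primary-suspect matching.  Extendable: the
pipeline accepts any CSV with columns `drug_id`, `type`, `variant`.

`smq_*.csv`, `soc_cardiac.csv` — **synthetic toy term lists**, NOT MedDRA.
MedDRA is licensed and cannot be redistributed; for a real analysis,
supply your own query files (columns `name`, `code`, `scope`, `pt`)
exported from a licensed MedDRA/SMQ distribution.  The bundled lists use
a small vocabulary of common clinical terms solely so that tests and the
synthetic-data generator can exercise the mapping machinery.
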