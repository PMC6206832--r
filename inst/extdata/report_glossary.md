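**Confidence levels.** A: the drug is regulator-approved for the patient's
cancer type. B: efficacy shown in well-powered clinical studies, preferably
phase 3. C: the drug is approved for a different cancer type, or was tested
in smaller studies for this cancer type. D: preclinical evidence only.

**Therapy sections.** Cancer type specific: approved for this indication.
Off-label: approved for a different indication. Investigational: not
approved; availability usually depends on a clinical trial.

**Variant frequency.** The fraction of sequencing reads supporting the
altered allele, in percent; subclonal variants show lower frequencies.

**Copy number.** The estimated number of genomic copies of the gene
(2 is normal in a diploid genome).

**Relative gene expression.** The boxplot summarizes the gene's expression
across a reference tumor cohort of the same cancer type (box: quartiles,
whiskers: range); the marker shows this patient's tumor.

**Mutational burden.** The number of non-synonymous protein-coding somatic
mutations; a high burden predicts response to CTLA-4 checkpoint blockade in
melanoma.

**Therapies potentially lacking benefit.** Treatments discouraged because of
resistance-associated variants, low mutational burden, or targets whose
amplification is not supported by gene expression.
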