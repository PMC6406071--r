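# Default scoring configuration: the canonical component parameter table.
# iv: ideal value  ip: inflection point  cs: curve slope  sq: squeeze
# ca: constant add (aggregation)  w: weight (geometric-mean exponent)
components:
  S_DP:   {iv: 0.05, ip: 0.25, cs: 2.5, sq: 1, ca: 0,  w: 4,
           label: "T-N expression level difference (pooled samples)"}
  S_DL:   {iv: 0.05, ip: 0.25, cs: 2.5, sq: 1, ca: 0,  w: 4,
           label: "T-N expression level difference (paired samples)"}
  S_DoO:  {iv: 0.1,  ip: 0.7,  cs: 2.5, sq: 1, ca: 10, w: 1,
           label: "T-N difference outliers, overexpression"}
  S_DoU:  {iv: 0.1,  ip: 0.7,  cs: 2.5, sq: 1, ca: 10, w: 1,
           label: "T-N difference outliers, underexpression"}
  S_DLc:  {iv: 0.1,  ip: 0.5,  cs: 2.5, sq: 1, ca: 5,  w: 2,
           label: "Cumulative T-N difference among paired samples"}
  S_EStD: {iv: 0.1,  ip: 0.3,  cs: 2,   sq: 1, ca: 5,  w: 1.5,
           label: "Expression stability: relative standard deviation"}
  S_EoH:  {iv: 0.1,  ip: 0.7,  cs: 2.5, sq: 1, ca: 5,  w: 0.75,
           label: "Expression stability: outliers, high expression"}
  S_EoL:  {iv: 0.1,  ip: 0.7,  cs: 2.5, sq: 1, ca: 5,  w: 0.75,
           label: "Expression stability: outliers, low expression"}
  S_EA:   {iv: 0.07, ip: 0.15, cs: 3,   sq: 1, ca: 0,  w: 6,
           label: "Average expression level"}
  S_Cp:   {iv: 2,    ip: 4,    cs: 3,   sq: 0.3, ca: 5, w: 0.3,
           label: "Clinical correlations: p-value"}
  S_Cr:   {iv: 0.1,  ip: 0.25, cs: 2.5, sq: 0.3, ca: 5, w: 0.2,
           label: "Clinical correlations: Spearman coefficient"}
anti:
  S_Mut:         {iv: 75, ip: 95, cs: 4, sq: 1,
                  label: "Percentile of mutation rate"}
  S_Isoforms:    {iv: 1,  ip: 3,  cs: 2, sq: 0.4,
                  label: "Number of transcript isoforms"}
  S_Pseudogenes: {iv: 0,  ip: 2,  cs: 2, sq: 0.4,
                  label: "Number of pseudogenes"}
clinical_characteristics:
  - pathologic_t
  - pathologic_n
  - pathologic_m
  - pathologic_stage
  - neoplasm_cancer_status
  - treatment_success
expression_measures:
  - cpm_tumor
  - cpm_normal
  - log2fc_paired
# feature extraction
trim: {lo: 10, hi: 90}
pseudocount: 0.25          # CPM added inside every log2 ratio
cpm_floor: 2               # trimmed-mean tumor CPM below this => S_EA sentinel 0
tmm: {logratio_trim: 0.3, sum_trim: 0.05, weighting: true}
# pan-cancer aggregation
pan_cancer: {k: -0.4, ca: 12}
# pair selection
pair: {score_threshold: 65, r_cutoff: 0.5, pool: tumor}
# GO penalty categories: points awarded if any keyword occurs
# (case-insensitive substring) in any GO term name of the gene
go_penalty:
  min_terms: 3
  insufficient_penalty: 10
  norm_exponent: 0.3
  categories:
    cell_cycle:
      points: 5
      keywords: [cell cycle, cell division, cell growth, cell proliferation,
                 apoptosis, apoptotic process, cell death, MAPK cascade,
                 tumor, oncogenic, apoptotic]
    differentiation:
      points: 4
      keywords: [cell differentiation, epithelial to mesenchymal transition,
                 mesenchymal to epithelial transition, stem cell, fetal,
                 embryonic, embryonal, embryo, gastrulation,
                 tissue development, cellular developmental process,
                 organ development]
    stress_response:
      points: 3
      keywords: [response to stress, DNA damage, DNA repair]
    immune_response:
      points: 2
      keywords: [inflammation, inflammatory, immune response,
                 T cell activation, macrophage activation, antigen]
    angiogenesis:
      points: 2
      keywords: [angiogenesis]
    intercellular:
      points: 2
      keywords: [cell communication, cell-cell signaling, cell adhesion,
                 cell motility, cell migration]
# cancer-related article detection: word matched in the title;
# a leading * matches any word ending ("*carcinoma" hits "adenocarcinoma")
pubmed:
  cancer_keywords: ["cancer", "tumor", "*carcinoma", "sarcoma", "glioma",
                    "glioblastoma"]
  # extension beyond the core list (editable)
  cancer_keywords_extended: ["leukemia", "lymphoma", "melanoma", "neoplasm",
                             "oncogene", "metastasis"]
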