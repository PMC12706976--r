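{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "acmgrules annotated-variant JSON dialect",
  "type": "object",
  "required": ["variants"],
  "properties": {
    "variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["chrom", "pos", "ref", "alt"],
        "additionalProperties": true,
        "properties": {
          "chrom": {"type": "string", "minLength": 1},
          "pos": {"type": "integer", "minimum": 1,
                  "description": "1-based position (VCF convention)"},
          "ref": {"type": "string", "minLength": 1},
          "alt": {"type": "string", "minLength": 1,
                  "description": "one alternate allele per record"},
          "variant_type": {"enum": ["SNV", "insertion", "deletion",
                                     "delins", "MNV"]},
          "gene": {"type": ["string", "null"]},
          "consequences": {
            "type": "array", "items": {"type": "string"},
            "description": "consequence terms on the canonical transcript; underscores and spaces are equivalent"
          },
          "transcripts": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id"],
              "properties": {
                "id": {"type": "string"},
                "consequences": {"type": "array",
                                 "items": {"type": "string"}},
                "aa_change": {"type": ["string", "null"]},
                "canonical": {"type": "boolean"}
              }
            }
          },
          "aa_change": {
            "type": ["string", "null"],
            "description": "compact protein change, e.g. R175H or p.R175H"
          },
          "clinvar": {
            "type": ["object", "null"],
            "properties": {
              "significance": {"type": "string"},
              "review_status": {"type": "string"},
              "id": {"type": "string"}
            },
            "description": "top ClinVar assertion for this variant"
          },
          "pubmed_ids": {"type": "array", "items": {"type": "string"}},
          "gene_disease": {
            "type": "array",
            "items": {
              "type": "object",
              "properties": {
                "disease": {"type": "string"},
                "inheritance": {"enum": ["AR", "AD", "XL", "other"]}
              }
            }
          },
          "dbsnp_ids": {"type": "array", "items": {"type": "string"}},
          "freq": {
            "type": "object",
            "description": "absent fields mean 'not observed in that resource', never 0",
            "properties": {
              "gnomad_af": {"type": "number", "minimum": 0, "maximum": 1},
              "gnomad_ac": {"type": "number", "minimum": 0},
              "gnomad_hom_count": {"type": "number", "minimum": 0},
              "gnomad_controls_ac": {"type": "number", "minimum": 0},
              "thousand_genomes_af": {"type": "number", "minimum": 0,
                                       "maximum": 1},
              "thousand_genomes_ac": {"type": "number", "minimum": 0},
              "topmed_af": {"type": "number", "minimum": 0, "maximum": 1},
              "topmed_ac": {"type": "number", "minimum": 0},
              "topmed_hom_count": {"type": "number", "minimum": 0},
              "hemizygous_male_count": {"type": "number", "minimum": 0},
              "homozygous_female_count": {"type": "number", "minimum": 0}
            }
          },
          "scores": {
            "type": "object",
            "properties": {
              "phylop": {"type": "number"},
              "gerp": {"type": "number"},
              "revel": {"type": "number", "minimum": 0, "maximum": 1},
              "dann": {"type": "number", "minimum": 0, "maximum": 1},
              "absplice": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        }
      }
    }
  }
}
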