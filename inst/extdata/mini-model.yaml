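# Miniature Biolink-flavoured data model: categories and predicates are
# single-parent trees; prefix_categories drives automatic typing; prefixes
# drives CURIE <-> IRI conversion. Substitute a fuller file of the same
# schema to use another model.
default_category: biolink:NamedThing
categories:
  biolink:NamedThing: null
  biolink:GeneOrGeneProduct: biolink:NamedThing
  biolink:Gene: biolink:GeneOrGeneProduct
  biolink:Protein: biolink:GeneOrGeneProduct
  biolink:ChemicalEntity: biolink:NamedThing
  biolink:Disease: biolink:NamedThing
  biolink:PhenotypicFeature: biolink:NamedThing
  biolink:OntologyClass: biolink:NamedThing
predicates:
  biolink:related_to: null
  biolink:interacts_with: biolink:related_to
  biolink:subclass_of: biolink:related_to
  biolink:has_phenotype: biolink:related_to
  biolink:treats: biolink:related_to
  biolink:associated_with: biolink:related_to
prefix_categories:
  HP: biolink:PhenotypicFeature
  MONDO: biolink:Disease
  CHEBI: biolink:ChemicalEntity
  GO: biolink:OntologyClass
  HGNC: biolink:Gene
  UniProtKB: biolink:Protein
  FOODON: biolink:OntologyClass
prefixes:
  HP: "http://purl.obolibrary.org/obo/HP_"
  MONDO: "http://purl.obolibrary.org/obo/MONDO_"
  CHEBI: "http://purl.obolibrary.org/obo/CHEBI_"
  GO: "http://purl.obolibrary.org/obo/GO_"
  FOODON: "http://purl.obolibrary.org/obo/FOODON_"
  HGNC: "http://identifiers.org/hgnc/"
  UniProtKB: "http://identifiers.org/uniprot/"
  biolink: "https://w3id.org/biolink/vocab/"
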