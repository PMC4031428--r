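<?xml version="1.0" encoding="UTF-8"?>
<phylo_dataset format_version="1.0" name="synthetic_2024">
  <sources>
    <source citation_key="evans1996_01">
      <bibliographic entry_type="article">
        <author>Evans, A.</author>
        <author>Adams, B.</author>
        <title>Phylogenetic relationships, study 1</title>
        <year>1996</year>
        <journal>Journal of Synthetic Phylogenetics</journal>
      </bibliographic>
      <source_tree>
        <tree_string>(Genus11_sp02,((Genus06_sp02,(Genus04_sp02,Genus05_sp01)),((Genus10_sp02,((((Genus12_sp01,Genus14_sp01),Genus05_sp03),Genus10_sp03),Genus12_sp02)),(Genus09_sp02,Genus08_sp01))));</tree_string>
        <character type="molecular" name="cytb"/>
        <analysis_used>Bayesian</analysis_used>
        <fossil_status>all_extant</fossil_status>
        <page_ref>393</page_ref>
      </source_tree>
    </source>
    <source citation_key="evans2009_02">
      <bibliographic entry_type="article">
        <author>Evans, A.</author>
        <author>Baker, B.</author>
        <title>Phylogenetic relationships, study 2</title>
        <year>2009</year>
        <journal>Journal of Synthetic Phylogenetics</journal>
      </bibliographic>
      <source_tree>
        <tree_string>(Genus04_sp02,(Genus05_sp03,(Genus02_sp02,(Genus09_sp02,Genus08_sp01))));</tree_string>
        <character type="molecular" name="12S rRNA"/>
        <character type="molecular" name="RAG1"/>
        <analysis_used>likelihood</analysis_used>
        <fossil_status>all_extant</fossil_status>
        <page_ref>147</page_ref>
      </source_tree>
      <source_tree>
        <tree_string>(Genus11_sp02,((((Genus06_sp01,Genus14_sp01),Genus08_sp01),Genus06_sp02),((Genus10_sp02,Genus05_sp02),Genus02_sp02)));</tree_string>
        <character type="molecular" name="RAG1"/>
        <character type="behavioural" name="vocalisation"/>
        <analysis_used>parsimony</analysis_used>
        <fossil_status>all_extant</fossil_status>
        <page_ref>118</page_ref>
      </source_tree>
    </source>
    <source citation_key="baker1995_03">
      <bibliographic entry_type="article">
        <author>Baker, A.</author>
        <author>Clark, B.</author>
        <title>Phylogenetic relationships, study 3</title>
        <year>1995</year>
        <journal>Journal of Synthetic Phylogenetics</journal>
      </bibliographic>
      <source_tree>
        <tree_string>(Genus04_sp01,(Genus08_sp03,((Genus13_sp01,Genus05_sp02),(Genus08_sp01,(Genus05_sp03,((Genus10_sp02,Genus11_sp02),Genus07_sp03))))));</tree_string>
        <character type="molecular" name="RAG1"/>
        <character type="morphological" name="osteology"/>
        <character type="morphological" name="dentition"/>
        <analysis_used>parsimony</analysis_used>
        <fossil_status>all_extant</fossil_status>
        <page_ref>421</page_ref>
      </source_tree>
    </source>
  </sources>
  <history>
    <event timestamp="1970-01-01T00:00:00" operation="generate" parameters="seed=2024 nSources=3 taxonPool=40"/>
  </history>
</phylo_dataset>
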