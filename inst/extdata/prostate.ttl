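@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .
@prefix ilxtr: <http://uri.interlex.org/tgbugs/uris/readable/> .
@prefix UBERON: <http://purl.obolibrary.org/obo/UBERON_> .
@prefix NCBITaxon: <http://purl.obolibrary.org/obo/NCBITaxon_> .
@prefix PATO: <http://purl.obolibrary.org/obo/PATO_> .
@prefix partOf: <http://purl.obolibrary.org/obo/BFO_0000050> .
@prefix prostate: <http://uri.interlex.org/tgbugs/uris/readable/sparc-nlp/prostate/> .

UBERON:0000045 a owl:Class ;
    rdfs:label "ganglion" .

UBERON:0001021 a owl:Class ;
    rdfs:label "nerve" .

UBERON:0001816 a owl:Class ;
    rdfs:label "nerve plexus" ;
    rdfs:subClassOf UBERON:0001021 .

UBERON:0002367 a owl:Class ;
    rdfs:label "prostate gland" .

UBERON:0005453 a owl:Class ;
    rdfs:label "inferior mesenteric ganglion" ;
    rdfs:subClassOf UBERON:0000045 .

UBERON:0006134 a owl:Class ;
    rdfs:label "nerve fiber" .

UBERON:0006447 a owl:Class ;
    rdfs:label "L5 segment of lumbar spinal cord" .

UBERON:0006449 a owl:Class ;
    rdfs:label "L3 segment of lumbar spinal cord" .

UBERON:0006450 a owl:Class ;
    rdfs:label "L2 segment of lumbar spinal cord" .

UBERON:0006451 a owl:Class ;
    rdfs:label "L4 segment of lumbar spinal cord" .

UBERON:0018683 a owl:Class ;
    rdfs:label "lumbar splanchnic nerve" ;
    rdfs:subClassOf UBERON:0001021 .

NCBITaxon:9615 rdfs:label "Canis familiaris" .

prostate:24 a owl:Class ;
    rdfs:label "neuron type prostate 24" ;
    skos:prefLabel "L2-L5 spinal cord to inferior mesenteric ganglion via lumbar splanchic nerve" ;
    ilxtr:reference "PMID:10473279" ;
    ilxtr:neuronPartialOrder
        ( "blank"
            ( UBERON:0006447
                ( UBERON:0018683
                    ( UBERON:0005453 )
                )
            )
            ( UBERON:0006450
                ( UBERON:0018683 )
            )
            ( UBERON:0006449
                ( UBERON:0018683 )
            )
            ( UBERON:0006451
                ( UBERON:0018683 )
            )
        ) ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf (
            ilxtr:NeuronSparcNlp
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasInstanceInTaxon ;
              owl:someValuesFrom NCBITaxon:9615 ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasBiologicalSex ;
              owl:someValuesFrom PATO:0000384 ]
            [ a owl:Class ;
              owl:complementOf [ a owl:Restriction ;
                  owl:onProperty ilxtr:hasBiologicalSex ;
                  owl:someValuesFrom PATO:0000383 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAnatomicalSystemPhenotype ;
              owl:someValuesFrom ilxtr:SympatheticPreGanglionicPhenotype ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasSomaLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0006447 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasSomaLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0006449 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasSomaLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0006450 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasSomaLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0006451 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0018683 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonPresynapticElementIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0005453 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasForwardConnectionPhenotype ;
              owl:someValuesFrom prostate:25 ]
        ) ] .

prostate:25 a owl:Class ;
    rdfs:label "neuron type prostate 25" ;
    skos:prefLabel "neuron type prostate 25" ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf (
            ilxtr:NeuronSparcNlp
        ) ] .

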