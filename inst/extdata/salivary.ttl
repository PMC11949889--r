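@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .
@prefix ilxtr: <http://uri.interlex.org/tgbugs/uris/readable/> .
@prefix UBERON: <http://purl.obolibrary.org/obo/UBERON_> .
@prefix ILX: <http://uri.interlex.org/base/ilx_> .
@prefix partOf: <http://purl.obolibrary.org/obo/BFO_0000050> .
@prefix salivary: <http://uri.interlex.org/tgbugs/uris/readable/sparc-nlp/salivary/> .

ILX:0793101 a owl:Class ;
    rdfs:label "superior salivatory nucleus" .

ILX:0793102 a owl:Class ;
    rdfs:label "greater petrosal nerve" ;
    ilxtr:isPartOf UBERON:0001647 ;
    rdfs:subClassOf UBERON:0001021 .

ILX:0793103 a owl:Class ;
    rdfs:label "vidian nerve" ;
    skos:altLabel "nerve of pterygoid canal" ;
    rdfs:subClassOf UBERON:0001021 .

ILX:0793104 a owl:Class ;
    rdfs:label "pterygopalatine ganglion" ;
    rdfs:subClassOf UBERON:0000045 .

UBERON:0000045 a owl:Class ;
    rdfs:label "ganglion" .

UBERON:0001021 a owl:Class ;
    rdfs:label "nerve" .

UBERON:0001647 a owl:Class ;
    rdfs:label "facial nerve" ;
    rdfs:subClassOf UBERON:0001021 .

UBERON:0001816 a owl:Class ;
    rdfs:label "nerve plexus" ;
    rdfs:subClassOf UBERON:0001021 .

UBERON:0006134 a owl:Class ;
    rdfs:label "nerve fiber" .

salivary:1 a owl:Class ;
    rdfs:label "neuron type salivary 1" ;
    skos:prefLabel "superior salivatory nucleus to pterygopalatine ganglion via facial nerve, greater petrosal nerve and vidian nerve" ;
    ilxtr:neuronPartialOrder
        ( "blank"
            ( ILX:0793101
                ( UBERON:0001647
                    ( ILX:0793102
                        ( ILX:0793103
                            ( ILX:0793104 )
                        )
                    )
                )
            )
        ) ;
    owl:equivalentClass [ a owl:Class ;
        owl:intersectionOf (
            ilxtr:NeuronApinatSimple
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAnatomicalSystemPhenotype ;
              owl:someValuesFrom ilxtr:ParasympatheticPreGanglionicPhenotype ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasSomaLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom ILX:0793101 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom ILX:0793102 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom ILX:0793103 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonLocatedIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom UBERON:0001647 ] ]
            [ a owl:Restriction ;
              owl:onProperty ilxtr:hasAxonPresynapticElementIn ;
              owl:someValuesFrom [ a owl:Restriction ;
                  owl:onProperty partOf: ;
                  owl:someValuesFrom ILX:0793104 ] ]
        ) ] .

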