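@prefix sc: <http://stepcoach.org/ns#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

sc:ActivityData
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:ActivityDataValue
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:ActivityDevice
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:ActivityLevelDaily
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:detects
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityDevice ;
  rdfs:range sc:Stimulus .

sc:featureOfInterest
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Observation ;
  rdfs:range sc:FeatureOfInterest .

sc:FeatureOfInterest
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:hasActivityLevel
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:ActivityLevelDaily .

sc:hasBeenCollectedBy
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityData ;
  rdfs:range sc:ActivityDataValue .

sc:hasHealthRecord
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:HealthRecord .

sc:hasIntervalDay
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:StepPrediction .

sc:hasMeasurementCapability
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityDevice ;
  rdfs:range sc:MeasurementCapability .

sc:hasOutput
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityDevice ;
  rdfs:range sc:SensorOutput .

sc:hasPersonalData
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:PersonalData .

sc:hasPreferences
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:Preferences .

sc:hasProperty
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:FeatureOfInterest ;
  rdfs:range sc:Property .

sc:hasReceivedRecommendation
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:Recommendation .

sc:hasStatus
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Participant ;
  rdfs:range sc:ParticipantStatus .

sc:hasTimeStamp
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityDataValue ;
  rdfs:domain sc:HealthRecord ;
  rdfs:domain sc:Questionnaire ;
  rdfs:domain sc:Recommendation ;
  rdfs:range sc:TemporalEntity .

sc:HealthRecord
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:isPropertyOf
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Property ;
  rdfs:range sc:FeatureOfInterest .

sc:MeasurementCapability
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Observation
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:observationResult
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Observation ;
  rdfs:range sc:SensorOutput .

sc:observedBy
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:Observation ;
  rdfs:range sc:Sensor .

sc:observes
  rdf:type owl:ObjectProperty ;
  rdfs:domain sc:ActivityDevice ;
  rdfs:range sc:Property .

sc:Participant
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:ParticipantStatus
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:PersonalData
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Preferences
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Property
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Questionnaire
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Recommendation
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Sensor
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:SensorOutput
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:StepPrediction
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:Stimulus
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .

sc:TemporalEntity
  rdf:type owl:Class ;
  rdfs:subClassOf owl:Thing .
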