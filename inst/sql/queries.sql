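-- Reference relational formulations of the eight audit queries, written
-- as common table expressions over the CDM store's table layout (one
-- delimited file per table; load them into any SQL engine to reproduce
-- the R implementations in queries.R). Concept ids are resolved by name
-- from CONCEPT; the local "operating room visit" concept tags OR visit
-- details. These files document the queries; the package's R functions
-- are the executable implementation.

-- Q1: number of operations per year and per specialty department
WITH or_concept AS (
  SELECT concept_id FROM concept WHERE name = 'operating room visit'
),
or_visits AS (
  SELECT vd.*
  FROM visit_detail vd
  JOIN or_concept oc ON vd.visit_detail_concept_id = oc.concept_id
)
SELECT CAST(strftime('%Y', ov.visit_detail_start_datetime) AS INT) AS year,
       dep.care_site_name AS department,
       COUNT(*) AS n_operations
FROM or_visits ov
LEFT JOIN care_site_link l ON l.room_care_site_id = ov.care_site_id
LEFT JOIN care_site dep ON dep.care_site_id = l.department_care_site_id
GROUP BY 1, 2
ORDER BY 1, 2;

-- Q2: anesthesia procedure during an outpatient visit
WITH outpatient AS (
  SELECT concept_id FROM concept WHERE name = 'outpatient stay'
),
or_visits AS (
  SELECT vd.* FROM visit_detail vd
  JOIN concept c ON vd.visit_detail_concept_id = c.concept_id
  WHERE c.name = 'operating room visit'
)
SELECT ov.visit_detail_id
FROM or_visits ov
JOIN visit_occurrence vo ON vo.visit_occurrence_id = ov.visit_occurrence_id
JOIN outpatient o ON vo.visit_concept_id = o.concept_id
ORDER BY 1;

-- Q3: operations with fast-track surgery and no admission to the PACU
WITH or_visits AS (
  SELECT vd.* FROM visit_detail vd
  JOIN concept c ON vd.visit_detail_concept_id = c.concept_id
  WHERE c.name = 'operating room visit'
),
pacu_periods AS (
  SELECT p.visit_detail_id
  FROM period p
  JOIN concept c ON p.period_concept_id = c.concept_id
  WHERE c.name = 'PACU period'
)
SELECT ov.visit_detail_id
FROM or_visits ov
WHERE ov.visit_detail_id NOT IN (SELECT visit_detail_id FROM pacu_periods)
ORDER BY 1;

-- Q4: operations with MAP < 65 mmHg within 30 minutes of inducing
-- anesthesia (start of P1 in [start of P2, start of P2 + 30 min))
WITH p1 AS (
  SELECT p.* FROM period p
  JOIN concept c ON p.period_concept_id = c.concept_id
  WHERE c.name = 'hypotension episode (MAP<65 mmHg)'
),
p2 AS (
  SELECT p.* FROM period p
  JOIN concept c ON p.period_concept_id = c.concept_id
  WHERE c.name = 'anesthesia period'
)
SELECT DISTINCT p1.visit_detail_id
FROM p1
JOIN p2 ON p1.visit_detail_id = p2.visit_detail_id
WHERE p1.start_datetime >= p2.start_datetime
  AND p1.start_datetime < datetime(p2.start_datetime, '+30 minutes')
ORDER BY 1;

-- Q5: rescue drugs within 15 minutes of the first drop of MAP below 65
WITH p1 AS (
  SELECT p.visit_detail_id, MIN(p.start_datetime) AS first_start
  FROM period p
  JOIN concept c ON p.period_concept_id = c.concept_id
  WHERE c.name = 'hypotension episode (MAP<65 mmHg)'
  GROUP BY p.visit_detail_id
),
rescue AS (
  SELECT de.*, c.name AS ingredient
  FROM drug_exposure de
  JOIN concept c ON de.drug_concept_id = c.concept_id
  WHERE c.name IN ('norepinephrine', 'epinephrine', 'ephedrine',
                   'phenylephrine', 'dobutamine', 'atropine')
)
SELECT r.ingredient, COUNT(*) AS n_administrations
FROM rescue r
JOIN p1 ON p1.visit_detail_id = r.visit_detail_id
WHERE r.drug_exposure_start_datetime >= p1.first_start
  AND r.drug_exposure_start_datetime < datetime(p1.first_start, '+15 minutes')
GROUP BY 1
ORDER BY 1;

-- Q6: length of stay by ASA status
WITH asa AS (
  SELECT co.visit_occurrence_id,
         CAST(REPLACE(co.condition_source_value, 'ASA ', '') AS INT) AS asa
  FROM condition_occurrence co
  JOIN concept c ON co.condition_concept_id = c.concept_id
  WHERE c.name = 'ASA physical status'
)
SELECT asa.asa,
       COUNT(DISTINCT vo.visit_occurrence_id) AS n_stays,
       (julianday(vo.visit_end_datetime) - julianday(vo.visit_start_datetime))
         AS los_days  -- aggregate to median/IQR client-side
FROM visit_occurrence vo
JOIN asa ON asa.visit_occurrence_id = vo.visit_occurrence_id
GROUP BY asa.asa;

-- Q7: operations followed by a stay in the intensive care unit
WITH or_visits AS (
  SELECT vd.* FROM visit_detail vd
  JOIN concept c ON vd.visit_detail_concept_id = c.concept_id
  WHERE c.name = 'operating room visit'
),
icu AS (
  SELECT vd.* FROM visit_detail vd
  JOIN concept c ON vd.visit_detail_concept_id = c.concept_id
  WHERE c.name = 'intensive care unit visit'
)
SELECT DISTINCT vd1.visit_detail_id
FROM or_visits vd1
JOIN icu vd2 ON vd1.visit_occurrence_id = vd2.visit_occurrence_id
WHERE vd2.visit_detail_start_datetime > vd1.visit_detail_end_datetime
ORDER BY 1;

-- Q8: characterization of the Mallampati grade (regex extraction of the
-- templated pattern "Mallampati: <I-IV|1-4>" is done client-side; the
-- relational part is the aggregation by extracted grade)
SELECT grade, COUNT(*) AS n
FROM (SELECT note_id, /* extract_mallampati(note_text) AS */ note_text AS grade
      FROM note)
GROUP BY grade;
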